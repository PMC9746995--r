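# Pool simulator: barcoded, multiplexed paired-end amplicon reads with
# known per-sample diploid genotypes, substitution error and barcode
# mistagging. Serves as the ground-truth fixture generator for every
# downstream stage.

#' Construct and validate a genotype specification
#'
#' The genotype specification states, per (sample, locus, site), the
#' true diploid genotype the simulator must emit. Heterozygous sites
#' place the alternate allele on one of the two haplotypes; each
#' simulated fragment then draws a haplotype with probability 1/2.
#'
#' @param entries data.frame with columns `sample_id`, `locus_id`,
#'   `insert_offset` (0-based position within the insert), `ref`, `alt`,
#'   `genotype` (one of `hom_ref`, `het`, `hom_alt`).
#' @param panel an `amp_panel`; used to check that `ref` matches the
#'   insert base and that sites avoid primer regions.
#' @param sheet optional `sample_sheet`; when given, sample ids are
#'   checked against it.
#' @return a `data.table` of class `genotype_spec`.
#' @export
genotype_spec <- function(entries, panel, sheet = NULL) {
  gs <- data.table::as.data.table(entries)
  req <- c("sample_id", "locus_id", "insert_offset", "ref", "alt", "genotype")
  if (!all(req %in% names(gs))) {
    stop("genotype spec needs columns: ", paste(req, collapse = ", "))
  }
  gs <- gs[, req, with = FALSE]
  if (!all(gs$genotype %in% c("hom_ref", "het", "hom_alt"))) {
    stop("genotype must be hom_ref, het or hom_alt")
  }
  if (!is.null(sheet)) {
    bad <- setdiff(gs$sample_id, sheet$sample_id)
    if (length(bad)) stop("unknown sample: ", paste(bad, collapse = ", "))
  }
  bad_loc <- setdiff(gs$locus_id, panel$loci$locus_id)
  if (length(bad_loc)) stop("unknown locus: ", paste(bad_loc, collapse = ", "))
  for (lid in unique(gs$locus_id)) {
    row <- panel$loci[panel$loci$locus_id == lid, ]
    ins <- panel$inserts[[lid]]
    sub <- gs[gs$locus_id == lid, ]
    flen <- nchar(row$fwd_primer)
    rlen <- nchar(row$rev_primer)
    if (any(sub$insert_offset < 0L | sub$insert_offset >= nchar(ins))) {
      stop(lid, ": site offset outside insert")
    }
    if (any(sub$insert_offset < flen |
            sub$insert_offset >= nchar(ins) - rlen)) {
      stop(lid, ": simulated site falls inside a primer region")
    }
    obs <- substr(rep(ins, nrow(sub)), sub$insert_offset + 1L,
                  sub$insert_offset + 1L)
    if (any(obs != sub$ref)) {
      stop(lid, ": ref allele does not match insert base at offset ",
           paste(sub$insert_offset[obs != sub$ref], collapse = ", "))
    }
  }
  data.table::setattr(gs, "class", c("genotype_spec", class(gs)))
  gs[]
}

#' Draw a random cohort genotype specification
#'
#' For each requested site, per-sample diploid genotypes are drawn from
#' Hardy-Weinberg proportions at the stated alternate allele frequency.
#'
#' @param panel an `amp_panel`.
#' @param sheet a `sample_sheet`.
#' @param sites data.frame with columns `locus_id`, `insert_offset`,
#'   `alt_freq`, and optionally `alt` (a concrete base; default a random
#'   base differing from the reference).
#' @param seed integer RNG seed.
#' @return a `genotype_spec` covering every sample in the sheet at every
#'   site.
#' @export
random_genotype_spec <- function(panel, sheet, sites, seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sites <- data.table::as.data.table(sites)
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i]
    ins <- panel$inserts[[s$locus_id]]
    ref <- substr(ins, s$insert_offset + 1L, s$insert_offset + 1L)
    alt <- if ("alt" %in% names(s) && !is.na(s$alt)) s$alt else
      sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    p <- s$alt_freq
    g <- sample(c("hom_ref", "het", "hom_alt"), nrow(sheet), replace = TRUE,
                prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
    out[[i]] <- data.table::data.table(
      sample_id = sheet$sample_id, locus_id = s$locus_id,
      insert_offset = s$insert_offset, ref = ref, alt = alt, genotype = g)
  }
  genotype_spec(data.table::rbindlist(out), panel, sheet)
}

#' Simulator configuration
#'
#' @param coverage read pairs per (sample, amplicon) combination
#'   (default 100). Ignored when `total_pairs` is given.
#' @param total_pairs optional total read pairs for the pool, drawn
#'   uniformly (or by `efficiency` weights) over sample x amplicon
#'   combinations; reproduces pool-level accounting such as 50,000 pairs
#'   over 220 amplicons.
#' @param read_length bases per mate (default 250, the platform's 250bp
#'   read pairs).
#' @param base_error_rate per-base substitution probability (default 0).
#' @param mistag_rate probability that a pair is emitted with a valid
#'   forward and valid reverse barcode whose combination is absent from
#'   the sample sheet (index-hopping style; default 0).
#' @param quality_model `"constant"` (all bases Q37) or `"two_level"`
#'   (erroneous bases get `q_low`, the rest `q_high`), the latter to
#'   exercise the base-quality filter.
#' @param q_high,q_low phred scores for the two-level model.
#' @param efficiency optional named numeric of per-locus relative
#'   amplification efficiencies (default 1 for every locus).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(coverage = 100L, total_pairs = NULL,
                       read_length = 250L, base_error_rate = 0,
                       mistag_rate = 0, quality_model = c("constant", "two_level"),
                       q_high = 37L, q_low = 20L, efficiency = NULL,
                       seed = 1L) {
  quality_model <- match.arg(quality_model)
  if (base_error_rate < 0 || base_error_rate > 1) stop("base_error_rate in [0,1]")
  if (mistag_rate < 0 || mistag_rate > 1) stop("mistag_rate in [0,1]")
  if (coverage < 0) stop("coverage must be >= 0")
  structure(list(coverage = as.integer(coverage),
                 total_pairs = if (is.null(total_pairs)) NULL else as.integer(total_pairs),
                 read_length = as.integer(read_length),
                 base_error_rate = base_error_rate,
                 mistag_rate = mistag_rate,
                 quality_model = quality_model,
                 q_high = as.integer(q_high), q_low = as.integer(q_low),
                 efficiency = efficiency, seed = as.integer(seed)),
            class = "sim_config")
}

inject_errors <- function(seqs, rate) {
  # returns list(seqs, err_pos): err_pos is a list of integer positions
  n <- length(seqs)
  err_pos <- vector("list", n)
  if (rate > 0 && n > 0L) {
    lens <- nchar(seqs)
    n_err <- stats::rbinom(n, lens, rate)
    hit <- which(n_err > 0L)
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      pos <- sort(sample.int(lens[i], n_err[i]))
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
      seqs[i] <- paste(ch, collapse = "")
      err_pos[[i]] <- pos
    }
  }
  list(seqs = seqs, err_pos = err_pos)
}

qual_strings <- function(seqs, err_pos, cfg) {
  lens <- nchar(seqs)
  hi <- rawToChar(as.raw(cfg$q_high + 33L))
  out <- strrep(hi, lens)
  if (cfg$quality_model == "two_level") {
    lo <- rawToChar(as.raw(cfg$q_low + 33L))
    hit <- which(lengths(err_pos) > 0L)
    for (i in hit) {
      ch <- strsplit(out[i], "", fixed = TRUE)[[1]]
      ch[err_pos[[i]]] <- lo
      out[i] <- paste(ch, collapse = "")
    }
  }
  out
}

#' Simulate a barcoded multiplexed amplicon pool
#'
#' Emits paired FASTQ files where each mate reads
#' 5'-(6bp barcode)(primer)(insert...)-3', mate 1 from the forward end
#' of the amplicon and mate 2 from the reverse end, together with a
#' truth table recording every pair's source sample, amplicon, haplotype
#' and mistag status. Heterozygous sites place the alternate allele on
#' haplotype 2 and each fragment draws its haplotype with probability
#' 1/2. Mistagged pairs carry a valid forward and valid reverse barcode
#' whose combination is absent from the sheet.
#'
#' @param panel an `amp_panel`.
#' @param sheet a `sample_sheet`; all its samples are simulated as one
#'   sequencing pool.
#' @param spec a `genotype_spec` (may have zero rows for an all
#'   wild-type pool).
#' @param cfg a `sim_config`.
#' @param out_prefix path prefix; writes `<prefix>.R1.fastq.gz`,
#'   `<prefix>.R2.fastq.gz` and `<prefix>.truth.tsv`.
#' @return list with `r1`, `r2`, `truth_path` and the truth `data.table`
#'   (`read_id`, `sample_id`, `locus_id`, `haplotype`, `mistag_flag`,
#'   `fwd_barcode`, `rev_barcode`).
#' @export
simulate_pool <- function(panel, sheet, spec, cfg = sim_config(),
                          out_prefix = tempfile("pool")) {
  stopifnot(inherits(panel, "amp_panel"), inherits(cfg, "sim_config"))
  if (nrow(spec)) {
    bad <- setdiff(spec$sample_id, sheet$sample_id)
    if (length(bad)) stop("genotype spec references unknown sample: ",
                          paste(bad, collapse = ", "))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)

  loci <- panel$loci$locus_id
  grid <- data.table::CJ(sample_id = sheet$sample_id, locus_id = loci,
                         sorted = FALSE)
  eff <- rep(1, length(loci)); names(eff) <- loci
  if (!is.null(cfg$efficiency)) eff[names(cfg$efficiency)] <- cfg$efficiency

  if (!is.null(cfg$total_pairs)) {
    w <- eff[grid$locus_id]
    idx <- sample.int(nrow(grid), cfg$total_pairs, replace = TRUE,
                      prob = w / sum(w))
  } else {
    reps <- as.integer(round(cfg$coverage * eff[grid$locus_id]))
    idx <- rep(seq_len(nrow(grid)), times = reps)
  }
  n <- length(idx)
  if (n == 0L) {
    truth <- data.table::data.table(read_id = character(),
                                    sample_id = character(),
                                    locus_id = character(),
                                    haplotype = integer(),
                                    mistag_flag = logical(),
                                    fwd_barcode = character(),
                                    rev_barcode = character())
    r1 <- paste0(out_prefix, ".R1.fastq.gz")
    r2 <- paste0(out_prefix, ".R2.fastq.gz")
    tp <- paste0(out_prefix, ".truth.tsv")
    write_fastq(character(), character(), character(), r1)
    write_fastq(character(), character(), character(), r2)
    data.table::fwrite(truth, tp, sep = "\t")
    return(list(r1 = r1, r2 = r2, truth_path = tp, truth = truth))
  }
  idx <- sample(idx)                       # shuffle arrival order
  src <- grid[idx]
  hap <- sample.int(2L, n, replace = TRUE)

  # haplotype sequences per (sample, locus)
  hap_fwd <- new.env(parent = emptyenv())
  hap_rev <- new.env(parent = emptyenv())
  get_hap <- function(sample, locus, which_hap, sense) {
    key <- paste0(sample, "\r", locus, "\r", which_hap)
    env <- if (sense) hap_fwd else hap_rev
    val <- env[[key]]
    if (is.null(val)) {
      ins <- panel$inserts[[locus]]
      sub <- spec[spec$sample_id == sample & spec$locus_id == locus, ]
      if (nrow(sub)) {
        apply_alt <- sub$genotype == "hom_alt" |
          (sub$genotype == "het" & which_hap == 2L)
        for (j in which(apply_alt)) {
          substr(ins, sub$insert_offset[j] + 1L, sub$insert_offset[j] + 1L) <-
            sub$alt[j]
        }
      }
      hap_fwd[[key]] <- ins
      hap_rev[[key]] <- revcomp(ins)
      val <- if (sense) ins else hap_rev[[key]]
    }
    val
  }
  key_all <- paste0(src$sample_id, "\r", src$locus_id, "\r", hap)
  need <- !duplicated(key_all)
  for (i in which(need)) {
    get_hap(src$sample_id[i], src$locus_id[i], hap[i], TRUE)
  }
  tmpl_fwd <- vapply(key_all, function(k) hap_fwd[[k]], character(1),
                     USE.NAMES = FALSE)
  tmpl_rev <- vapply(key_all, function(k) hap_rev[[k]], character(1),
                     USE.NAMES = FALSE)

  bc_f <- sheet$fwd_barcode[match(src$sample_id, sheet$sample_id)]
  bc_r <- sheet$rev_barcode[match(src$sample_id, sheet$sample_id)]

  # mistag injection: swap in a valid-but-unassigned barcode combination
  mistag <- stats::runif(n) < cfg$mistag_rate
  if (any(mistag)) {
    combos <- data.table::CJ(f = unique(sheet$fwd_barcode),
                             r = unique(sheet$rev_barcode))
    used <- paste(sheet$fwd_barcode, sheet$rev_barcode)
    free <- combos[!paste(combos$f, combos$r) %in% used]
    if (nrow(free) == 0L) stop("mistag_rate > 0 but every barcode ",
                               "combination is assigned in the sheet")
    pick <- free[sample.int(nrow(free), sum(mistag), replace = TRUE)]
    bc_f[mistag] <- pick$f
    bc_r[mistag] <- pick$r
  }

  ins_len <- cfg$read_length - BARCODE_LEN
  seq1 <- paste0(bc_f, substr(tmpl_fwd, 1L, ins_len))
  seq2 <- paste0(bc_r, substr(tmpl_rev, 1L, ins_len))
  e1 <- inject_errors(seq1, cfg$base_error_rate)
  e2 <- inject_errors(seq2, cfg$base_error_rate)
  q1 <- qual_strings(e1$seqs, e1$err_pos, cfg)
  q2 <- qual_strings(e2$seqs, e2$err_pos, cfg)

  ids <- sprintf("sim%07d", seq_len(n))
  truth <- data.table::data.table(read_id = ids, sample_id = src$sample_id,
                                  locus_id = src$locus_id, haplotype = hap,
                                  mistag_flag = mistag,
                                  fwd_barcode = bc_f, rev_barcode = bc_r)
  r1 <- paste0(out_prefix, ".R1.fastq.gz")
  r2 <- paste0(out_prefix, ".R2.fastq.gz")
  tp <- paste0(out_prefix, ".truth.tsv")
  write_fastq(ids, e1$seqs, q1, r1)
  write_fastq(ids, e2$seqs, q2, r2)
  data.table::fwrite(truth, tp, sep = "\t")
  list(r1 = r1, r2 = r2, truth_path = tp, truth = truth)
}

#' Per-amplicon read-count summary of a simulated pool
#'
#' One "amplicon" in pool accounting is one (sample, locus) product, as
#' in the published design's 11 loci x 20 mosquitoes = 220 amplicons per
#' pool.
#'
#' @param truth a truth table from [simulate_pool()].
#' @param panel,sheet optional; when given, combinations with zero reads
#'   are included in the summary grid.
#' @return list with `per_amplicon` (data.table `sample_id`, `locus_id`,
#'   `n`), `total`, `n_amplicons` and `mean_per_amplicon`.
#' @export
pool_depth_summary <- function(truth, panel = NULL, sheet = NULL) {
  truth <- data.table::as.data.table(truth)
  counts <- truth[, list(n = .N), by = c("sample_id", "locus_id")]
  if (!is.null(panel) && !is.null(sheet)) {
    grid <- data.table::CJ(sample_id = sheet$sample_id,
                           locus_id = panel$loci$locus_id, sorted = FALSE)
    counts <- merge(grid, counts, by = c("sample_id", "locus_id"),
                    all.x = TRUE, sort = FALSE)
    data.table::setnafill(counts, fill = 0L, cols = "n")
  }
  total <- sum(counts$n)
  list(per_amplicon = counts[], total = total,
       n_amplicons = nrow(counts),
       mean_per_amplicon = total / nrow(counts))
}
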