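# Cohort assembly: merge per-sample calls (deduplicating overlapping
# amplicons), apply cross-sample retention filters, annotate coding
# consequences and splice proximity, emit cohort VCF/TSV.

#' Merge per-sample call sets into a cohort table
#'
#' Sites are keyed by (chrom, pos, ref, alt) regardless of how many
#' amplicons cover them. Duplicate calls for one (sample, site) from
#' overlapping amplicons are merged by keeping the call with the higher
#' quality-passing depth; disagreeing duplicates are flagged
#' (`conflict`). Samples without a call at a site remain `missing` in
#' the genotype matrix.
#'
#' @param call_sets a list of per-sample call tables from
#'   [call_sample_variants()], or one combined data.table.
#' @param sheet a `sample_sheet` covering every sample (supplies the
#'   pool map).
#' @param panel an `amp_panel`.
#' @return an object of class `cohort_table`: list with `sites`
#'   (data.table `chrom`, `pos`, `ref`, `alt`, `locus_ids`), `calls`
#'   (merged long table), `sheet` and `panel`.
#' @export
merge_cohort <- function(call_sets, sheet, panel) {
  calls <- if (is.data.frame(call_sets)) data.table::as.data.table(call_sets)
           else data.table::rbindlist(call_sets)
  bad <- setdiff(unique(calls$sample_id), sheet$sample_id)
  if (length(bad)) stop("call set references sample absent from sheet: ",
                        paste(bad, collapse = ", "))
  # dedup overlapping-amplicon calls: per (sample, chrom, pos, ref) keep
  # the deepest call, flagging genotype disagreement
  data.table::setorderv(calls, c("sample_id", "chrom", "pos", "ref", "depth"),
                        order = c(1L, 1L, 1L, 1L, -1L))
  key <- c("sample_id", "chrom", "pos", "ref")
  ng <- calls[, list(n_gt = length(unique(.SD$genotype))), by = key]
  merged <- unique(calls, by = key)
  merged <- merge(merged, ng, by = key, sort = FALSE)
  merged$conflict <- merged$n_gt > 1L
  merged$n_gt <- NULL

  variant <- calls[!is.na(calls$alt)]
  sites <- variant[, list(locus_ids = paste(sort(unique(.SD$locus_id)),
                                            collapse = ",")),
                   by = c("chrom", "pos", "ref", "alt")]
  data.table::setorderv(sites, c("chrom", "pos", "ref", "alt"))
  structure(list(sites = sites[], calls = merged[], sheet = sheet,
                 panel = panel),
            class = "cohort_table")
}

#' Genotype matrix of a cohort table
#'
#' @param tab a `cohort_table`.
#' @return character matrix (sites x samples) of
#'   `hom_ref`/`het`/`hom_alt`/`missing`; rownames `chrom:pos:ref>alt`,
#'   colnames sample ids. A sample called with a different alternate
#'   allele at the site is `missing` for that site.
#' @export
genotype_matrix <- function(tab) {
  sites <- tab$sites
  samples <- tab$sheet$sample_id
  m <- matrix("missing", nrow = nrow(sites), ncol = length(samples),
              dimnames = list(paste0(sites$chrom, ":", sites$pos, ":",
                                     sites$ref, ">", sites$alt), samples))
  calls <- tab$calls
  for (i in seq_len(nrow(sites))) {
    s <- sites[i]
    sub <- calls[calls$chrom == s$chrom & calls$pos == s$pos &
                   calls$ref == s$ref, ]
    if (nrow(sub) == 0L) next
    ok_alt <- is.na(sub$alt) | sub$alt == s$alt
    gt <- ifelse(ok_alt, sub$genotype,
                 ifelse(sub$genotype == "hom_ref", "hom_ref", "missing"))
    m[i, sub$sample_id] <- gt
  }
  m
}

#' Apply the cohort retention filters
#'
#' A site is retained iff its carriers (samples with at least one
#' alternate allele, i.e. genotype `het` or `hom_alt`) number at least
#' `min_mosquitoes` AND span at least `min_pools` distinct pools —
#' the "present in more than one mosquito, across two independent
#' pools" rule. Dropped sites keep a reason flag (`singleton`,
#' `single_pool`). Idempotent.
#'
#' @param tab a `cohort_table`.
#' @param cfg a `filter_config`.
#' @return `tab` with `sites` gaining `carriers`, `pools`, `retained`,
#'   `reason` columns.
#' @export
apply_cohort_filters <- function(tab, cfg = filter_config()) {
  sites <- data.table::copy(tab$sites)
  sites$carriers <- 0L
  sites$pools <- 0L
  pool_of <- tab$sheet$pool_id
  names(pool_of) <- tab$sheet$sample_id
  gm <- genotype_matrix(tab)
  for (i in seq_len(nrow(sites))) {
    carrier <- colnames(gm)[gm[i, ] %in% c("het", "hom_alt")]
    sites$carriers[i] <- length(carrier)
    sites$pools[i] <- length(unique(pool_of[carrier]))
  }
  sites$retained <- sites$carriers >= cfg$min_mosquitoes &
    sites$pools >= cfg$min_pools
  sites$reason <- ifelse(sites$retained, "",
                         ifelse(sites$carriers < cfg$min_mosquitoes,
                                "singleton", "single_pool"))
  tab$sites <- sites[]
  tab
}

# ---- consequence annotation ------------------------------------------

complement_base <- function(b) chartr("ACGT", "TGCA", b)

# per-locus CDS segments in transcript order with resolved cds_offset
locus_cds <- function(panel, locus_id) {
  idx <- which(panel$cds$locus_id == locus_id)  # outside [: NSE-safe
  seg <- panel$cds[idx, ]
  if (nrow(seg) == 0L) return(seg)
  minus <- seg$strand[1L] == "-"
  data.table::setorderv(seg, "cds_start", order = if (minus) -1L else 1L)
  if (anyNA(seg$cds_offset)) {
    off <- (3L - seg$frame[1L]) %% 3L
    for (i in seq_len(nrow(seg))) {
      if (is.na(seg$cds_offset[i])) seg$cds_offset[i] <- off
      off <- seg$cds_offset[i] + (seg$cds_end[i] - seg$cds_start[i] + 1L)
    }
  }
  seg
}

translate_codon <- function(codon) {
  tab <- Biostrings::GENETIC_CODE
  aa <- tab[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Annotate the coding consequence of one site
#'
#' Exonic sites get their reference and alternate codons rebuilt from
#' the panel's CDS geometry (strand- and frame-aware) and translated
#' with the standard genetic code. Intronic sites within 8 bases of an
#' exon boundary are `splice_region`; exonic sites within 3 bases of a
#' boundary keep their coding effect and set `near_splice` (the 3/8
#' window convention of standard consequence callers). Codons that
#' extend beyond the amplicon or CDS segment are reported
#' `truncated_codon` rather than guessed.
#'
#' @param chrom,pos,ref,alt the site (1-based genomic position; SNVs
#'   only for codon effects — indels are reported as `indel`).
#' @param panel an `amp_panel`.
#' @return one-row data.table: `chrom`, `pos`, `ref`, `alt`, `locus_id`,
#'   `effect` (`synonymous`/`missense`/`stop_gained`/`intronic`/
#'   `splice_region`/`truncated_codon`/`indel`), `codon_ref`,
#'   `codon_alt`, `aa_pos`, `aa_ref`, `aa_alt`, `aa_change`,
#'   `dist_exon_boundary`, `near_splice`.
#' @export
annotate_consequence <- function(chrom, pos, ref, alt, panel) {
  hit_idx <- which(panel$loci$chrom == chrom & panel$loci$start <= pos &
                     panel$loci$end >= pos)  # outside [: NSE-safe
  hit <- panel$loci[hit_idx, ]
  if (nrow(hit) == 0L) stop("site ", chrom, ":", pos, " in no amplicon")
  base_row <- function(locus_id, effect, dist = NA_integer_,
                       near = FALSE, codon_ref = NA_character_,
                       codon_alt = NA_character_, aa_pos = NA_integer_,
                       aa_ref = NA_character_, aa_alt = NA_character_) {
    data.table::data.table(
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      locus_id = locus_id, effect = effect, codon_ref = codon_ref,
      codon_alt = codon_alt, aa_pos = aa_pos, aa_ref = aa_ref,
      aa_alt = aa_alt,
      aa_change = if (!is.na(aa_ref)) paste0(aa_ref, aa_pos, aa_alt)
                  else NA_character_,
      dist_exon_boundary = dist, near_splice = near)
  }
  # prefer an amplicon whose CDS covers the site
  chosen <- NULL
  for (i in seq_len(nrow(hit))) {
    seg <- locus_cds(panel, hit$locus_id[i])
    if (nrow(seg) && any(seg$cds_start <= pos & seg$cds_end >= pos)) {
      chosen <- hit[i]; break
    }
  }
  if (is.null(chosen)) chosen <- hit[1L]
  lid <- chosen$locus_id
  seg <- locus_cds(panel, lid)
  if (!is.na(ref) && !is.na(alt) && (nchar(ref) > 1L || nchar(alt) > 1L)) {
    return(base_row(lid, "indel"))
  }
  if (nrow(seg) == 0L) return(base_row(lid, "intronic"))

  inside <- which(seg$cds_start <= pos & seg$cds_end >= pos)
  if (length(inside) == 0L) {
    d <- min(abs(c(seg$cds_start - pos, seg$cds_end - pos)))
    eff <- if (d <= 8L) "splice_region" else "intronic"
    return(base_row(lid, eff, dist = as.integer(d)))
  }
  sg <- seg[inside[1L]]
  minus <- sg$strand == "-"
  dist_in <- min(pos - sg$cds_start, sg$cds_end - pos)
  near <- dist_in <= 2L  # within the first 3 exonic bases of a boundary
  cpos <- if (minus) sg$cds_offset + (sg$cds_end - pos)
          else sg$cds_offset + (pos - sg$cds_start)
  aa_pos <- cpos %/% 3L + 1L
  within <- cpos %% 3L
  # genomic positions of the codon in transcript order
  gpos <- if (minus) (pos + within) - 0:2 else (pos - within) + 0:2
  ins <- panel$inserts[[lid]]
  offs <- gpos - chosen$start
  if (any(offs < 0L | offs >= nchar(ins)) ||
      any(gpos < sg$cds_start | gpos > sg$cds_end)) {
    return(base_row(lid, "truncated_codon", dist = as.integer(dist_in),
                    near = near))
  }
  bases <- substr(rep(ins, 3L), offs + 1L, offs + 1L)
  if (minus) bases <- complement_base(bases)
  codon_ref <- paste(bases, collapse = "")
  mut_base <- if (minus) complement_base(alt) else alt
  bases_alt <- bases
  bases_alt[if (minus) (gpos == pos) else (gpos == pos)] <- mut_base
  codon_alt <- paste(bases_alt, collapse = "")
  aa_ref <- translate_codon(codon_ref)
  aa_alt <- translate_codon(codon_alt)
  eff <- if (is.na(aa_ref) || is.na(aa_alt)) "truncated_codon"
         else if (aa_alt == "*" && aa_ref != "*") "stop_gained"
         else if (aa_ref == aa_alt) "synonymous" else "missense"
  base_row(lid, eff, dist = as.integer(dist_in), near = near,
           codon_ref = codon_ref, codon_alt = codon_alt,
           aa_pos = as.integer(aa_pos), aa_ref = aa_ref, aa_alt = aa_alt)
}

#' Annotate every site of a cohort table
#' @param tab a `cohort_table`.
#' @param retained_only annotate only retained sites (default TRUE when
#'   filters have been applied).
#' @return data.table of per-site annotations (see
#'   [annotate_consequence()]).
#' @export
annotate_cohort <- function(tab, retained_only = "retained" %in% names(tab$sites)) {
  sites <- tab$sites
  if (retained_only && "retained" %in% names(sites)) {
    sites <- sites[sites$retained, ]
  }
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    out[[i]] <- annotate_consequence(sites$chrom[i], sites$pos[i],
                                     sites$ref[i], sites$alt[i], tab$panel)
  }
  data.table::rbindlist(out)
}

# ---- VCF output -------------------------------------------------------

gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
             missing = "./.")

#' Write a cohort table as multi-sample VCF 4.2
#'
#' One record per unique retained site (all sites if filters have not
#' been applied), samples as columns with GT, DP, AD and AR (allele
#' ratio) fields, consequence in INFO/CSQ when annotations are given.
#' Output is deterministic (no timestamps) and byte-stable under
#' write-parse-write.
#'
#' @param tab a `cohort_table`.
#' @param path output path.
#' @param annotations optional table from [annotate_cohort()].
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(tab, path, annotations = NULL) {
  sites <- tab$sites
  if ("retained" %in% names(sites)) sites <- sites[sites$retained, ]
  data.table::setorderv(sites, c("chrom", "pos", "ref", "alt"))
  samples <- tab$sheet$sample_id
  gm <- genotype_matrix(tab)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ampliseqr",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence|AminoAcidChange|Loci\">",
    "##INFO=<ID=LOCI,Number=1,Type=String,Description=\"Supporting amplicons\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Quality-passing depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">",
    "##FORMAT=<ID=AR,Number=1,Type=Float,Description=\"Major allele ratio\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  lines <- character(nrow(sites))
  calls <- tab$calls
  for (i in seq_len(nrow(sites))) {
    s <- sites[i]
    key <- paste0(s$chrom, ":", s$pos, ":", s$ref, ">", s$alt)
    info <- paste0("LOCI=", s$locus_ids)
    if (!is.null(annotations)) {
      an <- annotations[annotations$chrom == s$chrom &
                          annotations$pos == s$pos &
                          annotations$ref == s$ref &
                          annotations$alt == s$alt, ]
      if (nrow(an)) {
        info <- paste0("CSQ=", an$effect[1L], "|",
                       ifelse(is.na(an$aa_change[1L]), ".", an$aa_change[1L]),
                       ";", info)
      }
    }
    cells <- character(length(samples))
    for (k in seq_along(samples)) {
      sub <- calls[calls$sample_id == samples[k] & calls$chrom == s$chrom &
                     calls$pos == s$pos & calls$ref == s$ref, ]
      gt <- gm[key, samples[k]]
      if (nrow(sub) == 0L) {
        cells[k] <- "./.:0:0,0:."
      } else {
        ar <- sub$allele_ratio[1L]
        cells[k] <- paste0(gt_code[[gt]], ":", sub$depth[1L], ":",
                           sub$ad_ref[1L], ",", sub$ad_alt[1L], ":",
                           if (is.na(ar)) "." else as.character(round(ar, 4)))
      }
    }
    lines[i] <- paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS",
                        info, "GT:DP:AD:AR", cells), collapse = "\t")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}

#' Parse a cohort VCF written by [write_cohort_vcf()]
#'
#' @param path VCF path.
#' @return list with `sites` (data.table `chrom`, `pos`, `ref`, `alt`,
#'   `info`), `calls` (long data.table `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `genotype`, `depth`, `ad_ref`, `ad_alt`,
#'   `allele_ratio`) and `samples`.
#' @export
read_cohort_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "##")]
  chrom_line <- lines[startsWith(lines, "#CHROM")]
  if (length(chrom_line) != 1L) stop("not a VCF: missing #CHROM line")
  cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  sites <- list(); calls <- list()
  code_gt <- names(gt_code)
  names(code_gt) <- unname(gt_code)
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    sites[[length(sites) + 1L]] <- data.table::data.table(
      chrom = f[1L], pos = as.integer(f[2L]), ref = f[4L], alt = f[5L],
      info = f[8L])
    for (k in seq_along(samples)) {
      parts <- strsplit(f[9L + k], ":", fixed = TRUE)[[1]]
      ad <- strsplit(parts[3L], ",", fixed = TRUE)[[1]]
      calls[[length(calls) + 1L]] <- data.table::data.table(
        sample_id = samples[k], chrom = f[1L], pos = as.integer(f[2L]),
        ref = f[4L], alt = f[5L], genotype = unname(code_gt[[parts[1L]]]),
        depth = as.integer(parts[2L]), ad_ref = as.integer(ad[1L]),
        ad_alt = as.integer(ad[2L]),
        allele_ratio = if (parts[4L] == ".") NA_real_ else as.numeric(parts[4L]))
    }
  }
  list(header = hdr, sites = data.table::rbindlist(sites),
       calls = data.table::rbindlist(calls), samples = samples)
}

#' Retention report of a filtered cohort
#' @param tab a filtered `cohort_table`.
#' @param path optional TSV output path.
#' @return the report data.table (site, carriers, pools, retained,
#'   reason), invisibly written to `path` when given.
#' @export
retention_report <- function(tab, path = NULL) {
  if (!"retained" %in% names(tab$sites)) {
    stop("apply_cohort_filters() first")
  }
  rep <- tab$sites[, c("chrom", "pos", "ref", "alt", "carriers", "pools",
                       "retained", "reason"), with = FALSE]
  if (!is.null(path)) data.table::fwrite(rep, path, sep = "\t")
  rep[]
}
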