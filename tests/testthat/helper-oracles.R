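# Independent oracles and fixture builders used across the suite.
# Oracles deliberately re-derive results from first principles rather
# than reusing package internals.

# position-by-position IUPAC primer check (brute force)
oracle_primer_match <- function(primer, window, max_mismatch) {
  tab <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  p <- strsplit(primer, "")[[1]]
  w <- strsplit(window, "")[[1]]
  mm <- sum(vapply(seq_along(p), function(i) !(w[i] %in% tab[[p[i]]]),
                   logical(1)))
  list(match = mm <= max_mismatch, mismatches = mm)
}

# full affine-gap semi-global DP, scores only (independent of the C++
# implementation's traceback machinery)
oracle_glocal_score <- function(read, ref, match = 1, mismatch = -1,
                                open = -4, ext = -1) {
  r <- strsplit(read, "")[[1]]; f <- strsplit(ref, "")[[1]]
  m <- length(r); n <- length(f); NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, ] <- 0
  for (i in seq_len(m)) Y[i + 1, 1] <- open + i * ext
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (r[i] == f[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i + 1, j] + open + ext, X[i + 1, j] + ext)
      Y[i + 1, j + 1] <- max(M[i, j + 1] + open + ext, Y[i, j + 1] + ext)
    }
  }
  max(M[m + 1, ], Y[m + 1, ])
}

# Tajima's D by explicit chromosome-pair enumeration
oracle_tajima_d <- function(geno) {
  n <- 2L * nrow(geno)
  chrom <- matrix(0L, n, ncol(geno))
  for (i in seq_len(nrow(geno))) {
    chrom[2L * i - 1L, ] <- as.integer(geno[i, ] >= 1L)
    chrom[2L * i, ] <- as.integer(geno[i, ] == 2L)
  }
  S <- sum(apply(chrom, 2, function(col) any(col != col[1L])))
  if (S == 0L) return(NA_real_)
  pr <- utils::combn(n, 2)
  k <- mean(apply(pr, 2, function(p) sum(chrom[p[1L], ] != chrom[p[2L], ])))
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small hand-built panel (bypasses the 440-500bp production range) for
# annotation and merge tests
mini_panel <- function(insert, chrom = "1", start = 1001L, cds = NULL,
                       locus_id = "toyA", fwd_len = 5L, rev_len = 5L) {
  loci <- data.table::data.table(
    locus_id = locus_id, gene = "toy", chrom = chrom, start = start,
    end = start + nchar(insert) - 1L,
    fwd_primer = substr(insert, 1L, fwd_len),
    rev_primer = ampliseqr::revcomp(substr(insert, nchar(insert) - rev_len + 1L,
                                           nchar(insert))),
    length = nchar(insert), multiplex_group = 1L)
  if (is.null(cds)) {
    cds <- data.table::data.table(locus_id = character(), cds_start = integer(),
                                  cds_end = integer(), strand = character(),
                                  frame = integer(), cds_offset = integer())
  }
  inserts <- stats::setNames(insert, locus_id)
  structure(list(loci = loci, inserts = inserts, cds = cds,
                 known_sites = data.table::data.table(
                   locus_id = character(), pos = integer(),
                   ref_aa = character(), alt_aa = character(),
                   label = character())),
            class = "amp_panel")
}

# alignment rows for single-base "reads" covering offset 0 of a 1-base
# insert -- used to exercise the pileup/genotyping path site by site
site_alignments <- function(bases, quals = 37L) {
  n <- length(bases)
  data.table::data.table(
    pair_id = sprintf("r%05d", seq_len(n)), mate = 1L,
    insert_start = 0L, cigar = "1M", seq = bases,
    qual = vapply(rep_len(quals, n),
                  function(q) rawToChar(as.raw(q + 33L)), character(1)))
}

# one simulated two-pool study used by several tests (built lazily)
make_study <- function(n_samples = 8L, coverage = 60L, error = 0,
                       mistag = 0, seed = 101L, sites = NULL) {
  panel <- example_panel()
  sheet <- example_sheet(n_samples, 2L)
  if (is.null(sites)) {
    sites <- data.frame(locus_id = "Rdl_Aeg", insert_offset = 235L,
                        alt = "T", alt_freq = 0.6)
  }
  gs <- random_genotype_spec(panel, sheet, sites, seed = seed)
  cfg <- sim_config(coverage = coverage, base_error_rate = error,
                    mistag_rate = mistag, seed = seed)
  sims <- list()
  for (pid in unique(sheet$pool_id)) {
    sub <- sheet[sheet$pool_id == pid, ]
    sims[[pid]] <- simulate_pool(panel, sub,
                                 gs[gs$sample_id %in% sub$sample_id, ],
                                 cfg, out_prefix = tempfile(pid))
  }
  list(panel = panel, sheet = sheet, gs = gs, cfg = cfg, sims = sims)
}
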