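# Population-genetic and quality statistics: allele frequencies, MAF
# spectrum, Hardy-Weinberg chi-squared tests, Tajima's D, genotype
# concordance between call sets.

#' Per-site allele frequency and Hardy-Weinberg statistics
#'
#' Given diploid genotype counts, computes the alternate allele
#' frequency `p = (het + 2 hom_alt) / (2 n)`, the minor allele frequency
#' `min(p, 1-p)`, and a 1-df chi-squared goodness-of-fit test of the
#' observed genotype counts against Hardy-Weinberg expectations
#' `n (1-p)^2 / 2 n p (1-p) / n p^2` (no continuity correction).
#'
#' @param hom_ref,het,hom_alt genotype counts.
#' @param hwe_alpha significance threshold for the deviation flag
#'   (default 0.001, the convention used in panel reports).
#' @return list with `n`, `alt_freq`, `maf`, `chisq`, `p_value`,
#'   `hwe_flag` and the counts.
#' @export
site_stats <- function(hom_ref, het, hom_alt, hwe_alpha = 0.001) {
  n <- hom_ref + het + hom_alt
  if (n < 1L) stop("all-missing site: no genotypes to summarise")
  p <- (het + 2 * hom_alt) / (2 * n)
  q <- 1 - p
  obs <- c(hom_ref, het, hom_alt)
  expd <- n * c(q^2, 2 * p * q, p^2)
  nz <- expd > 0
  chisq <- sum((obs[nz] - expd[nz])^2 / expd[nz])
  p_value <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  if (any(expd[nz] < 5)) {
    warning("expected genotype count < 5; chi-squared approximation is weak",
            call. = FALSE)
  }
  list(n = n, hom_ref = hom_ref, het = het, hom_alt = hom_alt,
       alt_freq = p, maf = min(p, q), chisq = chisq, p_value = p_value,
       hwe_flag = p_value < hwe_alpha)
}

#' Per-site statistics for a whole cohort
#'
#' @param tab a `cohort_table` (filtered or not); only retained sites
#'   are summarised when filters have been applied.
#' @return data.table, one row per site, with genotype counts, carrier
#'   counts, alternate allele frequency (percent), MAF, HWE chi-squared
#'   and flag — the shape of a per-site report table.
#' @export
cohort_site_stats <- function(tab) {
  gm <- genotype_matrix(tab)
  sites <- tab$sites
  keep <- if ("retained" %in% names(sites)) which(sites$retained)
          else seq_len(nrow(sites))
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    g <- gm[i, ]
    cnt <- c(sum(g == "hom_ref"), sum(g == "het"), sum(g == "hom_alt"))
    st <- suppressWarnings(site_stats(cnt[1L], cnt[2L], cnt[3L]))
    out[[k]] <- data.table::data.table(
      chrom = sites$chrom[i], pos = sites$pos[i], ref = sites$ref[i],
      alt = sites$alt[i], n_genotyped = st$n,
      n_carriers = st$het + st$hom_alt,
      hom_ref = st$hom_ref, het = st$het, hom_alt = st$hom_alt,
      alt_freq_pct = 100 * st$alt_freq, maf = st$maf,
      hwe_chisq = st$chisq, hwe_p = st$p_value, hwe_flag = st$hwe_flag)
  }
  data.table::rbindlist(out)
}

#' Fraction of sites with minor allele frequency below a threshold
#' @param stats a [cohort_site_stats()] table, or any data.frame with a
#'   `maf` column.
#' @param threshold MAF cutoff (default 0.1).
#' @return fraction in \[0, 1\].
#' @export
maf_spectrum <- function(stats, threshold = 0.1) {
  if (!"maf" %in% names(stats)) stop("need a 'maf' column")
  if (nrow(stats) == 0L) stop("no sites")
  mean(stats$maf < threshold)
}

#' Tajima's D from an unphased diploid genotype matrix
#'
#' Genotypes are alternate-allele dosages 0/1/2 (rows = samples,
#' columns = biallelic sites); `n = 2 x samples` chromosomes. The mean
#' pairwise difference is computed from per-site allele counts,
#' `k = sum_sites 2 x (2n - x) / (2n (2n - 1))`, which equals the
#' average over all chromosome pairs and needs no phasing. Sites with
#' any missing genotype are dropped (listwise per site). `D` is the
#' standard normalized difference between `k` and Watterson's `S / a1`;
#' it is reported missing when `S = 0`.
#'
#' @param geno numeric matrix of 0/1/2 dosages (NA = missing).
#' @return object of class `tajima_result`: list with `n_chrom`, `S`,
#'   `k_bar`, the Watterson constants `a1`, `a2`, `b1`, `b2`, `c1`,
#'   `c2`, `e1`, `e2`, and `D` (NA when `S = 0`).
#' @export
tajimas_d <- function(geno) {
  geno <- as.matrix(geno)
  n_chrom <- 2L * nrow(geno)
  if (n_chrom < 2L || nrow(geno) < 1L) stop("need at least 2 chromosomes")
  complete <- colSums(is.na(geno)) == 0L
  geno <- geno[, complete, drop = FALSE]
  x <- colSums(geno)
  seg <- x > 0L & x < n_chrom
  S <- sum(seg)
  nn <- n_chrom
  k_bar <- sum(2 * x[seg] * (nn - x[seg])) / (nn * (nn - 1))
  i <- seq_len(nn - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (nn + 1) / (3 * (nn - 1))
  b2 <- 2 * (nn^2 + nn + 3) / (9 * nn * (nn - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (nn + 2) / (a1 * nn) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- if (S == 0L) NA_real_ else {
    (k_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  }
  structure(list(n_chrom = nn, S = S, k_bar = k_bar, a1 = a1, a2 = a2,
                 b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2,
                 D = D),
            class = "tajima_result")
}

#' @export
print.tajima_result <- function(x, ...) {
  cat(sprintf("Tajima's D: n = %d chromosomes, S = %d, k_bar = %.4f, D = %s\n",
              x$n_chrom, x$S, x$k_bar,
              if (is.na(x$D)) "undefined (S = 0)" else sprintf("%.4f", x$D)))
  invisible(x)
}

#' Tajima's D per amplicon (or pooled) for a cohort
#' @param tab a `cohort_table`.
#' @param per_locus compute one statistic per amplicon (default) or one
#'   over all sites concatenated (`FALSE`).
#' @return data.table with `locus_id` (or `"all"`), `n_chrom`, `S`,
#'   `k_bar`, `D`.
#' @export
cohort_tajimas_d <- function(tab, per_locus = TRUE) {
  gm <- genotype_matrix(tab)
  sites <- tab$sites
  keep <- if ("retained" %in% names(sites)) sites$retained
          else rep(TRUE, nrow(sites))
  dosage <- matrix(NA_real_, nrow = ncol(gm), ncol = nrow(gm))
  dosage[t(gm) == "hom_ref"] <- 0
  dosage[t(gm) == "het"] <- 1
  dosage[t(gm) == "hom_alt"] <- 2
  groups <- if (per_locus) {
    lid <- vapply(strsplit(sites$locus_ids, ",", fixed = TRUE), `[`,
                  character(1), 1L)
    split(seq_len(nrow(sites)), lid)
  } else list(all = seq_len(nrow(sites)))
  out <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    idx <- intersect(groups[[k]], which(keep))
    td <- tajimas_d(dosage[, idx, drop = FALSE])
    out[[k]] <- data.table::data.table(locus_id = names(groups)[k],
                                       n_chrom = td$n_chrom, S = td$S,
                                       k_bar = td$k_bar, D = td$D)
  }
  data.table::rbindlist(out)
}

#' Genotype concordance between two call sets
#'
#' Compares genotypes over the shared (sample, site) keys of two call
#' tables (replicate runs, or sequencing vs an external method such as
#' Sanger). Missing genotypes are excluded. With
#' `apply_reassignment = TRUE`, heterozygous calls in `a` whose allele
#' ratio is at least `hom_ratio_threshold` are recalled as homozygous
#' for their major allele before comparison — the borderline-ratio
#' reassignment that restores full concordance between replicates.
#'
#' @param a,b call tables with columns `sample_id`, `chrom`, `pos`,
#'   `genotype`, and (for `a` under reassignment) `allele_ratio`,
#'   `ad_ref`, `ad_alt`.
#' @param apply_reassignment logical (default FALSE).
#' @param cfg a `filter_config` (supplies the ratio threshold).
#' @return object of class `concordance_report`: `compared`,
#'   `concordant`, `percent`, `matrix` (called x reference), and
#'   `discordant` (data.table with allele ratios).
#' @export
concordance <- function(a, b, apply_reassignment = FALSE,
                        cfg = filter_config()) {
  a <- data.table::as.data.table(a)
  b <- data.table::as.data.table(b)
  key <- c("sample_id", "chrom", "pos")
  j <- merge(a, b[, c(key, "genotype"), with = FALSE], by = key,
             suffixes = c("", "_ref"))
  j <- j[j$genotype != "missing" & j$genotype_ref != "missing", ]
  if (nrow(j) == 0L) stop("no overlapping non-missing (sample, site) keys")
  called <- j$genotype
  if (apply_reassignment) {
    hit <- called == "het" & !is.na(j$allele_ratio) &
      j$allele_ratio >= cfg$hom_ratio_threshold
    called[hit] <- ifelse(j$ad_alt[hit] > j$ad_ref[hit], "hom_alt", "hom_ref")
  }
  eq <- called == j$genotype_ref
  lv <- c("hom_ref", "het", "hom_alt")
  mat <- table(factor(called, levels = lv),
               factor(j$genotype_ref, levels = lv),
               dnn = c("called", "reference"))
  disc <- j[!eq, c("sample_id", "chrom", "pos", "genotype",
                   "genotype_ref", "allele_ratio"), with = FALSE]
  structure(list(compared = nrow(j), concordant = sum(eq),
                 percent = 100 * sum(eq) / nrow(j), matrix = mat,
                 discordant = disc[]),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance: %d/%d genotypes agree (%.1f%%)\n",
              x$concordant, x$compared, x$percent))
  print(x$matrix)
  invisible(x)
}
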