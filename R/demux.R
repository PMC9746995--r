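# Dual 6bp-barcode demultiplexing: assign pooled read pairs to
# (mosquito, amplicon), discard mistagged combinations, trim barcode and
# primer bases.

# index of each barcode in `valid`, tolerating up to max_mm mismatches
# (NA where no match or ambiguous best match)
match_barcode <- function(bcs, valid, max_mm = 0L) {
  idx <- match(bcs, valid)
  if (max_mm > 0L && anyNA(idx)) {
    todo <- which(is.na(idx))
    vch <- strsplit(valid, "", fixed = TRUE)
    for (i in todo) {
      b <- strsplit(bcs[i], "", fixed = TRUE)[[1]]
      if (length(b) != BARCODE_LEN) next
      d <- vapply(vch, function(v) sum(v != b), integer(1))
      best <- which(d == min(d))
      if (min(d) <= max_mm && length(best) == 1L) idx[i] <- best
    }
  }
  idx
}

# n x n_amplicon matrix of IUPAC-aware mismatch counts for the primer of
# each amplicon read at string position `from`; NA = window unusable
primer_mm_matrix <- function(seqs, primers, from = BARCODE_LEN + 1L) {
  n <- length(seqs)
  out <- matrix(NA_integer_, nrow = n, ncol = length(primers))
  for (a in seq_along(primers)) {
    len <- nchar(primers[[a]])
    win <- substr(seqs, from, from + len - 1L)
    ok <- nchar(win) == len
    if (any(ok)) out[ok, a] <- primer_mismatches(primers[[a]], win[ok])
  }
  out
}

new_demux_stats <- function(total, assigned, mistag, unmatched, per_tab) {
  stopifnot(assigned + mistag + unmatched == total)
  structure(list(total_pairs = total, assigned = assigned, mistag = mistag,
                 unmatched = unmatched, per_sample_per_locus = per_tab),
            class = "demux_stats")
}

#' @export
print.demux_stats <- function(x, ...) {
  cat(sprintf("Demultiplexing: %d pairs; %d assigned (%.1f%%), %d mistag, %d unmatched\n",
              x$total_pairs, x$assigned,
              if (x$total_pairs) 100 * x$assigned / x$total_pairs else 0,
              x$mistag, x$unmatched))
  invisible(x)
}

#' Demultiplex a pooled paired-end run to (mosquito, amplicon)
#'
#' A pair is assigned iff (i) the first 6 bases of each mate match a
#' known barcode within `barcode_max_mismatch`; (ii) the (forward,
#' reverse) barcode combination exists in the sample sheet; and (iii)
#' the bases following the barcode match exactly one amplicon's primer
#' within `primer_max_mismatch` (IUPAC-aware) on both mates. Pairs with
#' individually valid barcodes whose combination is absent from the
#' sheet are counted `mistag` and discarded — the mistag-removal step of
#' the assay. Everything else (unknown barcode, failed or conflicting
#' primer match) is `unmatched`. Both read orientations are attempted
#' (forward barcode on mate 1, then on mate 2).
#'
#' Assigned reads are returned with barcode and primer bases trimmed;
#' the `fwd_*` columns always hold the sense-strand mate.
#'
#' @param r1,r2 FASTQ paths (plain or gzip) or data.tables from the
#'   internal reader; mates must be synchronized.
#' @param panel an `amp_panel`.
#' @param sheet a `sample_sheet` (one pool).
#' @param cfg a `filter_config`.
#' @return list with `groups` (data.table: `read_id`, `sample_id`,
#'   `locus_id`, `pool_id`, `fwd_seq`, `fwd_qual`, `rev_seq`,
#'   `rev_qual`) and `stats` (a `demux_stats`).
#' @export
demultiplex <- function(r1, r2, panel, sheet, cfg = filter_config()) {
  if (!is.data.frame(r1)) r1 <- read_fastq(r1)
  if (!is.data.frame(r2)) r2 <- read_fastq(r2)
  if (nrow(sheet) == 0L) stop("empty sample sheet")
  if (nrow(r1) != nrow(r2) || !all(r1$read_id == r2$read_id)) {
    stop("desynchronized mates: R1 and R2 read ids differ")
  }
  n <- nrow(r1)
  fwd_set <- unique(sheet$fwd_barcode)
  rev_set <- unique(sheet$rev_barcode)
  combo_key <- paste(sheet$fwd_barcode, sheet$rev_barcode)

  orient <- function(seq_f, seq_r) {
    fi <- match_barcode(substr(seq_f, 1L, BARCODE_LEN), fwd_set,
                        cfg$barcode_max_mismatch)
    ri <- match_barcode(substr(seq_r, 1L, BARCODE_LEN), rev_set,
                        cfg$barcode_max_mismatch)
    valid <- !is.na(fi) & !is.na(ri)
    samp <- rep(NA_integer_, length(seq_f))
    samp[valid] <- match(paste(fwd_set[fi[valid]], rev_set[ri[valid]]),
                         combo_key)
    list(valid_barcodes = valid, sample_idx = samp)
  }
  oA <- orient(r1$seq, r2$seq)
  oB <- orient(r2$seq, r1$seq)

  use_A <- !is.na(oA$sample_idx)
  use_B <- !use_A & !is.na(oB$sample_idx)
  has_combo <- use_A | use_B
  mistag <- !has_combo & (oA$valid_barcodes | oB$valid_barcodes)

  sample_idx <- ifelse(use_A, oA$sample_idx, oB$sample_idx)
  seq_f <- ifelse(use_A, r1$seq, r2$seq)
  qual_f <- ifelse(use_A, r1$qual, r2$qual)
  seq_r <- ifelse(use_A, r2$seq, r1$seq)
  qual_r <- ifelse(use_A, r2$qual, r1$qual)

  # primer identification on pairs with a sheet-valid combination
  amp <- rep(NA_integer_, n)
  cand <- which(has_combo)
  if (length(cand)) {
    mm_f <- primer_mm_matrix(seq_f[cand], panel$loci$fwd_primer)
    mm_r <- primer_mm_matrix(seq_r[cand], panel$loci$rev_primer)
    ok_f <- !is.na(mm_f) & mm_f <= cfg$primer_max_mismatch
    ok_r <- !is.na(mm_r) & mm_r <= cfg$primer_max_mismatch
    both <- ok_f & ok_r
    n_hit <- rowSums(both)
    one <- n_hit == 1L
    amp[cand[one]] <- max.col(both[one, , drop = FALSE], ties.method = "first")
    multi <- which(n_hit > 1L)
    for (i in multi) {
      tot <- mm_f[i, ] + mm_r[i, ]
      tot[!both[i, ]] <- NA_integer_
      best <- which(tot == min(tot, na.rm = TRUE))
      if (length(best) == 1L) amp[cand[i]] <- best
    }
  }
  assigned <- has_combo & !is.na(amp)

  groups <- data.table::data.table(
    read_id = r1$read_id[assigned],
    sample_id = sheet$sample_id[sample_idx[assigned]],
    locus_id = panel$loci$locus_id[amp[assigned]],
    pool_id = sheet$pool_id[sample_idx[assigned]],
    fwd_seq = seq_f[assigned], fwd_qual = qual_f[assigned],
    rev_seq = seq_r[assigned], rev_qual = qual_r[assigned]
  )
  if (nrow(groups)) {
    flen <- nchar(panel$loci$fwd_primer)[amp[assigned]] + BARCODE_LEN
    rlen <- nchar(panel$loci$rev_primer)[amp[assigned]] + BARCODE_LEN
    groups$fwd_seq <- substr(groups$fwd_seq, flen + 1L, nchar(groups$fwd_seq))
    groups$fwd_qual <- substr(groups$fwd_qual, flen + 1L, nchar(groups$fwd_qual))
    groups$rev_seq <- substr(groups$rev_seq, rlen + 1L, nchar(groups$rev_seq))
    groups$rev_qual <- substr(groups$rev_qual, rlen + 1L, nchar(groups$rev_qual))
  }
  per_tab <- groups[, list(n = .N), by = c("sample_id", "locus_id")]
  stats <- new_demux_stats(n, sum(assigned), sum(mistag),
                           n - sum(assigned) - sum(mistag), per_tab)
  list(groups = groups[], stats = stats)
}

#' Trim barcode and primer bases from an assigned read pair
#'
#' Removes the 6bp barcode plus the matched primer from the 5' end of
#' each mate, trimming the quality string in lockstep. The remaining
#' mate-1 sequence starts at the insert position immediately downstream
#' of the forward primer.
#'
#' @param pair list with `seq1`, `qual1`, `seq2`, `qual2` (mate 1
#'   carrying the forward barcode).
#' @param amplicon one row of `panel$loci` (the matched amplicon).
#' @return the trimmed pair (same shape).
#' @export
trim_technical <- function(pair, amplicon) {
  t1 <- BARCODE_LEN + nchar(amplicon$fwd_primer)
  t2 <- BARCODE_LEN + nchar(amplicon$rev_primer)
  if (t1 >= nchar(pair$seq1) || t2 >= nchar(pair$seq2)) {
    stop("trim length exceeds read length")
  }
  list(seq1 = substr(pair$seq1, t1 + 1L, nchar(pair$seq1)),
       qual1 = substr(pair$qual1, t1 + 1L, nchar(pair$qual1)),
       seq2 = substr(pair$seq2, t2 + 1L, nchar(pair$seq2)),
       qual2 = substr(pair$qual2, t2 + 1L, nchar(pair$qual2)))
}

#' Write demultiplexed read groups as per-(sample, locus) FASTQ files
#'
#' @param groups the `groups` table from [demultiplex()].
#' @param dir output directory; files are named
#'   `<sample>.<locus>.R1.fastq.gz` / `.R2.fastq.gz`.
#' @return character vector of paths written, invisibly.
#' @export
write_demux_fastq <- function(groups, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  keys <- unique(groups[, c("sample_id", "locus_id")])
  for (i in seq_len(nrow(keys))) {
    g <- groups[groups$sample_id == keys$sample_id[i] &
                  groups$locus_id == keys$locus_id[i], ]
    base <- file.path(dir, paste0(keys$sample_id[i], ".", keys$locus_id[i]))
    p1 <- paste0(base, ".R1.fastq.gz")
    p2 <- paste0(base, ".R2.fastq.gz")
    write_fastq(g$read_id, g$fwd_seq, g$fwd_qual, p1)
    write_fastq(g$read_id, g$rev_seq, g$rev_qual, p2)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
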