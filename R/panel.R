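# Amplicon panel data model: loci, primers, reference inserts, CDS
# geometry, known resistance sites, sample sheet and filter thresholds.

#' IUPAC expansion table
#'
#' Named list mapping each of the 15 IUPAC nucleotide codes to the set of
#' concrete bases it stands for.
#' @keywords internal
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# 15x4 logical lookup: IUPAC_MATRIX[code, base]
IUPAC_MATRIX <- local({
  m <- matrix(FALSE, nrow = length(IUPAC_CODES), ncol = 4,
              dimnames = list(names(IUPAC_CODES), c("A", "C", "G", "T")))
  for (code in names(IUPAC_CODES)) m[code, IUPAC_CODES[[code]]] <- TRUE
  m
})

#' Does an observed base fall in the expansion set of an IUPAC code?
#'
#' @param pattern_base character vector of single IUPAC codes (degenerate
#'   codes allowed).
#' @param observed_base character vector of single concrete bases
#'   (A/C/G/T only). Recycled against `pattern_base`.
#' @return logical vector, `TRUE` where the observed base is in the
#'   expansion set of the pattern code.
#' @examples
#' iupac_match("R", "A")  # TRUE
#' iupac_match("R", "C")  # FALSE
#' @export
iupac_match <- function(pattern_base, observed_base) {
  pattern_base <- toupper(pattern_base)
  observed_base <- toupper(observed_base)
  bad <- !pattern_base %in% rownames(IUPAC_MATRIX)
  if (any(bad)) {
    stop("invalid IUPAC code: ", paste(unique(pattern_base[bad]), collapse = ", "))
  }
  bad_obs <- !observed_base %in% c("A", "C", "G", "T")
  if (any(bad_obs)) {
    stop("observed base must be A/C/G/T, got: ",
         paste(unique(observed_base[bad_obs]), collapse = ", "))
  }
  n <- max(length(pattern_base), length(observed_base))
  pattern_base <- rep_len(pattern_base, n)
  observed_base <- rep_len(observed_base, n)
  IUPAC_MATRIX[cbind(pattern_base, observed_base)]
}

#' Reverse complement of (possibly degenerate) nucleotide strings
#' @param x character vector of sequences over the IUPAC alphabet.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Count IUPAC-aware mismatches between a primer and sequence windows
#'
#' Internal vectorized worker: compares `primer` position-by-position
#' against each window (all windows must have `nchar(primer)` characters).
#' @return integer vector of mismatch counts; NA_integer_ where a window
#'   contains a non-ACGT character.
#' @keywords internal
primer_mismatches <- function(primer, windows) {
  primer <- toupper(primer)
  windows <- toupper(windows)
  len <- nchar(primer)
  if (any(nchar(windows) != len)) stop("window length must equal primer length")
  pch <- strsplit(primer, "", fixed = TRUE)[[1]]
  if (any(!pch %in% rownames(IUPAC_MATRIX))) {
    stop("invalid IUPAC code in primer: ", primer)
  }
  mm <- integer(length(windows))
  valid <- rep(TRUE, length(windows))
  for (i in seq_len(len)) {
    obs <- substr(windows, i, i)
    known <- obs %in% c("A", "C", "G", "T")
    valid <- valid & known
    hit <- logical(length(obs))
    hit[known] <- IUPAC_MATRIX[cbind(rep(pch[i], sum(known)), obs[known])]
    mm <- mm + as.integer(!hit)
  }
  mm[!valid] <- NA_integer_
  mm
}

#' Match a degenerate primer against a sequence window
#'
#' @param primer IUPAC nucleotide string.
#' @param sequence_window concrete (A/C/G/T) string of the same length.
#' @param max_mismatch maximum tolerated number of positions failing
#'   [iupac_match()].
#' @return list with elements `match` (logical) and `mismatches` (integer).
#' @export
match_primer <- function(primer, sequence_window, max_mismatch = 0L) {
  if (nchar(primer) != nchar(sequence_window)) {
    stop("window length (", nchar(sequence_window),
         ") must equal primer length (", nchar(primer), ")")
  }
  mm <- primer_mismatches(primer, sequence_window)
  if (is.na(mm)) stop("sequence window must contain only A/C/G/T")
  list(match = mm <= max_mismatch, mismatches = mm)
}

#' Filtering and genotyping thresholds
#'
#' Bundles the quality filters applied during pileup construction and
#' genotyping, plus the cohort retention and demultiplexing tolerances.
#' Defaults follow the assay's published filters: minimum base quality
#' Q30, minimum site depth 50, minimum allele depth 10, heterozygote
#' reassignment to homozygous at allele ratio >= 0.8, retention of sites
#' seen in more than one mosquito across at least two pools.
#'
#' @param min_base_quality phred score below which a base call is excluded
#'   from allele depths (default 30).
#' @param min_depth minimum quality-passing depth for a genotype call;
#'   below it the genotype is `missing` (default 50).
#' @param min_allele_depth minimum reads supporting an allele for it to be
#'   considered at all (default 10).
#' @param hom_ratio_threshold allele ratio (major / top-two depth) at or
#'   above which a call is homozygous for the major allele (default 0.8;
#'   must lie in (0.5, 1]).
#' @param min_mosquitoes minimum number of carrier mosquitoes for a site
#'   to be retained in the cohort (default 2, i.e. "more than one").
#' @param min_pools minimum number of distinct pools among carriers
#'   (default 2).
#' @param barcode_max_mismatch mismatches tolerated when matching the 6bp
#'   barcodes (default 0, exact).
#' @param primer_max_mismatch IUPAC-aware mismatches tolerated when
#'   matching primers (default 2).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_base_quality = 30L, min_depth = 50L,
                          min_allele_depth = 10L, hom_ratio_threshold = 0.8,
                          min_mosquitoes = 2L, min_pools = 2L,
                          barcode_max_mismatch = 0L, primer_max_mismatch = 2L) {
  cfg <- list(
    min_base_quality = as.integer(min_base_quality),
    min_depth = as.integer(min_depth),
    min_allele_depth = as.integer(min_allele_depth),
    hom_ratio_threshold = as.numeric(hom_ratio_threshold),
    min_mosquitoes = as.integer(min_mosquitoes),
    min_pools = as.integer(min_pools),
    barcode_max_mismatch = as.integer(barcode_max_mismatch),
    primer_max_mismatch = as.integer(primer_max_mismatch)
  )
  nums <- unlist(cfg[names(cfg) != "hom_ratio_threshold"])
  if (any(is.na(nums)) || any(nums < 0)) stop("all thresholds must be non-negative")
  if (!(cfg$hom_ratio_threshold > 0.5 && cfg$hom_ratio_threshold <= 1)) {
    stop("hom_ratio_threshold must lie in (0.5, 1]")
  }
  structure(cfg, class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Filter configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

BARCODE_LEN <- 6L

#' Read and validate a sample sheet
#'
#' The sample sheet maps each mosquito to its dual 6bp barcode
#' combination and sequencing pool. Tab-separated with header columns
#' `sample_id`, `fwd_barcode`, `rev_barcode`, `pool_id`.
#'
#' @param path file path, or a data.frame with the same columns.
#' @return a `data.table` of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- if (is.data.frame(path)) {
    data.table::as.data.table(path)
  } else {
    data.table::fread(path, sep = "\t", colClasses = "character")
  }
  req <- c("sample_id", "fwd_barcode", "rev_barcode", "pool_id")
  if (!all(req %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  sheet <- sheet[, req, with = FALSE]
  for (col in req) data.table::set(sheet, j = col, value = as.character(sheet[[col]]))
  if (nrow(sheet) == 0L) stop("empty sample sheet")
  bc <- c(sheet$fwd_barcode, sheet$rev_barcode)
  if (any(nchar(bc) != BARCODE_LEN)) stop("all barcodes must be exactly 6bp")
  if (any(grepl("[^ACGT]", bc))) stop("barcodes must contain only A/C/G/T")
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sheet")
  combo <- paste(sheet$pool_id, sheet$fwd_barcode, sheet$rev_barcode)
  if (anyDuplicated(combo)) {
    stop("duplicate (fwd_barcode, rev_barcode) combination within a pool")
  }
  data.table::setattr(sheet, "class", c("sample_sheet", class(sheet)))
  sheet[]
}

#' Write a sample sheet
#' @param sheet a `sample_sheet`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  data.table::fwrite(data.table::as.data.table(unclass(sheet)), path, sep = "\t")
  invisible(path)
}

#' Parse and validate an amplicon panel
#'
#' A panel is described by up to four plain-text files:
#' \describe{
#'   \item{panel_file}{TSV with header `locus_id`, `gene`, `chrom`,
#'     `start`, `end`, `fwd_primer`, `rev_primer`, `length`,
#'     `multiplex_group`. Coordinates are 1-based inclusive genomic
#'     positions of the amplicon (primer-to-primer).}
#'   \item{insert_fasta}{FASTA of the reference insert (full amplicon
#'     sequence including primer sites, genome forward strand), one
#'     record per locus_id.}
#'   \item{cds_file}{optional TSV `locus_id`, `cds_start`, `cds_end`,
#'     `strand`, `frame` and optionally `cds_offset` (coding bases of the
#'     transcript preceding the segment; enables absolute amino-acid
#'     numbering).}
#'   \item{known_sites_file}{optional TSV `locus_id`, `pos`, `ref_aa`,
#'     `alt_aa`, `label` of literature resistance positions.}
#' }
#'
#' Validation enforces: declared length equals insert length and lies in
#' `length_range`; the forward primer IUPAC-matches the insert 5' end and
#' the reverse complement of the reverse primer matches its 3' end;
#' inserts are strictly A/C/G/T (degenerate bases are legal in primers
#' only); CDS segments per locus are ordered and non-overlapping.
#'
#' @param panel_file path to the panel TSV.
#' @param insert_fasta path to the insert FASTA.
#' @param cds_file,known_sites_file optional companion files.
#' @param length_range allowed declared-length interval (default
#'   `c(440, 500)`, this panel's ~450-500bp design).
#' @return an object of class `amp_panel` with elements `loci` (data.table),
#'   `inserts` (named character), `cds` and `known_sites` (data.tables).
#' @export
parse_panel <- function(panel_file, insert_fasta, cds_file = NULL,
                        known_sites_file = NULL, length_range = c(440L, 500L)) {
  loci <- data.table::fread(panel_file, sep = "\t",
                            colClasses = list(character = c("locus_id", "gene",
                                                            "chrom", "fwd_primer",
                                                            "rev_primer")))
  req <- c("locus_id", "gene", "chrom", "start", "end", "fwd_primer",
           "rev_primer", "length", "multiplex_group")
  if (!all(req %in% names(loci))) {
    stop("panel file must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(loci) == 0L) stop("no amplicons defined")
  loci <- loci[, req, with = FALSE]
  fa <- Biostrings::readDNAStringSet(insert_fasta)
  inserts <- toupper(as.character(fa))
  names(inserts) <- sub("\\s.*$", "", names(fa))

  cds <- if (is.null(cds_file)) {
    data.table::data.table(locus_id = character(), cds_start = integer(),
                           cds_end = integer(), strand = character(),
                           frame = integer(), cds_offset = integer())
  } else {
    x <- data.table::fread(cds_file, sep = "\t",
                           colClasses = list(character = c("locus_id", "strand")))
    if (!"cds_offset" %in% names(x)) x$cds_offset <- NA_integer_
    x
  }
  known <- if (is.null(known_sites_file)) {
    data.table::data.table(locus_id = character(), pos = integer(),
                           ref_aa = character(), alt_aa = character(),
                           label = character())
  } else {
    data.table::fread(known_sites_file, sep = "\t",
                      colClasses = list(character = c("locus_id", "ref_aa",
                                                      "alt_aa", "label")))
  }
  panel <- structure(list(loci = loci, inserts = inserts, cds = cds,
                          known_sites = known),
                     class = "amp_panel")
  validate_panel(panel, length_range = length_range)
  panel
}

#' Validate an amplicon panel object
#' @param panel an `amp_panel`.
#' @param length_range allowed declared-length interval.
#' @return `panel`, invisibly; stops on the first violated invariant.
#' @export
validate_panel <- function(panel, length_range = c(440L, 500L)) {
  loci <- panel$loci
  if (nrow(loci) == 0L) stop("no amplicons defined")
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus_id in panel")
  missing_ins <- setdiff(loci$locus_id, names(panel$inserts))
  if (length(missing_ins)) {
    stop("missing insert for locus: ", paste(missing_ins, collapse = ", "))
  }
  for (i in seq_len(nrow(loci))) {
    row <- loci[i]
    ins <- panel$inserts[[row$locus_id]]
    if (grepl("[^ACGT]", ins)) {
      stop(row$locus_id, ": insert contains non-A/C/G/T characters ",
           "(degenerate bases are legal in primers only)")
    }
    if (nchar(ins) != row$length) {
      stop(row$locus_id, ": declared length ", row$length,
           " != insert length ", nchar(ins))
    }
    if (row$length < length_range[1] || row$length > length_range[2]) {
      stop(row$locus_id, ": declared length ", row$length,
           " outside panel range [", length_range[1], ", ", length_range[2], "]")
    }
    if (row$end - row$start + 1L != row$length) {
      stop(row$locus_id, ": genomic span (end - start + 1) != declared length")
    }
    flen <- nchar(row$fwd_primer)
    rlen <- nchar(row$rev_primer)
    mm_f <- primer_mismatches(row$fwd_primer, substr(ins, 1L, flen))
    if (is.na(mm_f) || mm_f > 0L) {
      stop(row$locus_id, ": forward primer does not match insert 5' end")
    }
    mm_r <- primer_mismatches(revcomp(row$rev_primer),
                              substr(ins, nchar(ins) - rlen + 1L, nchar(ins)))
    if (is.na(mm_r) || mm_r > 0L) {
      stop(row$locus_id, ": reverse primer (reverse-complemented) does not ",
           "match insert 3' end")
    }
  }
  if (nrow(panel$cds)) {
    bad_locus <- setdiff(panel$cds$locus_id, loci$locus_id)
    if (length(bad_locus)) stop("CDS segment for unknown locus: ",
                                paste(bad_locus, collapse = ", "))
    if (!all(panel$cds$strand %in% c("+", "-"))) stop("CDS strand must be + or -")
    if (!all(panel$cds$frame %in% 0:2)) stop("CDS frame must be 0, 1 or 2")
    for (lid in unique(panel$cds$locus_id)) {
      seg <- panel$cds[panel$cds$locus_id == lid, ]
      if (any(seg$cds_end < seg$cds_start)) stop(lid, ": CDS end < start")
      o <- order(seg$cds_start)
      if (!identical(o, seq_len(nrow(seg)))) stop(lid, ": CDS segments not ordered")
      if (nrow(seg) > 1L &&
          any(seg$cds_start[-1L] <= seg$cds_end[-nrow(seg)])) {
        stop(lid, ": overlapping CDS segments")
      }
      has_off <- !is.na(seg$cds_offset)
      if (any(has_off)) {
        implied <- (3L - (seg$cds_offset[has_off] %% 3L)) %% 3L
        if (any(implied != seg$frame[has_off])) {
          stop(lid, ": frame inconsistent with cds_offset")
        }
      }
    }
  }
  if (nrow(panel$known_sites)) {
    bad <- setdiff(panel$known_sites$locus_id, loci$locus_id)
    if (length(bad)) stop("known site for unknown locus: ",
                          paste(bad, collapse = ", "))
    for (i in seq_len(nrow(panel$known_sites))) {
      ks <- panel$known_sites[i]
      row <- loci[loci$locus_id == ks$locus_id, ]
      if (ks$pos < row$start || ks$pos > row$end) {
        stop(ks$locus_id, ": known site position ", ks$pos,
             " outside amplicon [", row$start, ", ", row$end, "]")
      }
    }
  }
  invisible(panel)
}

#' Write a panel to its file set
#'
#' Inverse of [parse_panel()]: writing then re-parsing yields an
#' identical panel.
#'
#' @param panel an `amp_panel`.
#' @param prefix path prefix; files `<prefix>.panel.tsv`,
#'   `<prefix>.inserts.fasta` and, when present, `<prefix>.cds.tsv` and
#'   `<prefix>.known_sites.tsv` are written.
#' @return named character vector of the paths written, invisibly.
#' @export
write_panel <- function(panel, prefix) {
  paths <- c(panel = paste0(prefix, ".panel.tsv"),
             inserts = paste0(prefix, ".inserts.fasta"))
  data.table::fwrite(panel$loci, paths[["panel"]], sep = "\t")
  seqs <- Biostrings::DNAStringSet(panel$inserts)
  Biostrings::writeXStringSet(seqs, paths[["inserts"]], width = 80L)
  if (nrow(panel$cds)) {
    paths[["cds"]] <- paste0(prefix, ".cds.tsv")
    data.table::fwrite(panel$cds, paths[["cds"]], sep = "\t")
  }
  if (nrow(panel$known_sites)) {
    paths[["known_sites"]] <- paste0(prefix, ".known_sites.tsv")
    data.table::fwrite(panel$known_sites, paths[["known_sites"]], sep = "\t")
  }
  invisible(paths)
}

#' @export
print.amp_panel <- function(x, ...) {
  cat(sprintf("Amplicon panel: %d loci across %d gene(s)\n",
              nrow(x$loci), length(unique(x$loci$gene))))
  cat(sprintf("  lengths %d-%dbp; %d CDS segment(s); %d known site(s)\n",
              min(x$loci$length), max(x$loci$length),
              nrow(x$cds), nrow(x$known_sites)))
  invisible(x)
}

# Map a genomic position to a 0-based insert offset for one locus.
# Inserts are stored on the genome forward strand, so the mapping is a
# simple shift.
genomic_to_offset <- function(panel, locus_id, pos) {
  hit <- which(panel$loci$locus_id == locus_id)
  if (length(hit) != 1L) stop("unknown locus: ", locus_id)
  as.integer(pos - panel$loci$start[hit])
}

offset_to_genomic <- function(panel, locus_id, offset) {
  hit <- which(panel$loci$locus_id == locus_id)
  if (length(hit) != 1L) stop("unknown locus: ", locus_id)
  as.integer(panel$loci$start[hit] + offset)
}
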