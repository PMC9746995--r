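# Built-in demonstration panel: the published 11-amplicon insecticide
# resistance assay (vgsc, ace-1, rdl) with synthetic reference inserts.
#
# Primer sequences, amplicon lengths and multiplex groups are the real
# assay design; the insert sequences are SYNTHETIC (seeded random bodies
# with the primer sequences grafted at the ends), so no genome download
# is needed. Known resistance codons (rdl A296S, ace-1 G119S, vgsc
# V1016G and F1534C) are engineered into the synthetic inserts at
# coordinates consistent with the literature, so consequence annotation
# and resistance reporting behave realistically.

EXAMPLE_LOCI <- data.frame(
  locus_id = c("DomainI", "DomainIIIExon35", "Rdl_Aeg", "Ace1",
               "DomainIIS4", "DomainII", "DomainIIIExon36", "DomainIV",
               "DomainIIExon26", "DomainIIIExon33_34", "DomainIVS6"),
  gene = c("vgsc", "vgsc", "rdl", "ace-1", "vgsc", "vgsc", "vgsc", "vgsc",
           "vgsc", "vgsc", "vgsc"),
  chrom = c("3", "3", "2", "3", "3", "3", "3", "3", "3", "3", "3"),
  start = c(316080000L, 315938950L, 41847555L, 161499900L, 316000000L,
            315990000L, 315938400L, 315932000L, 315984000L, 315939500L,
            315931000L),
  fwd_primer = c("TTTCGTCTAATGACCCAAGA", "GGATCCAGATCATGAACGAY",
                 "CCAACCGATGTATCTTCTTC", "TCGCYTRGCCGAAGCCGT",
                 "TCTAGATTTAGYGACTCCAR", "ACTCRTTCATGATCGTGTTC",
                 "GTGTCATCATCGACAACTTC", "GCGATCTSATCGAGAAGTA",
                 "TCACCTTATGCTAAGACTTCA", "AACTCTCTATTCCCGCTTG",
                 "TGTTGGACGGTATCATCAA"),
  rev_primer = c("ARAGAWTTCGCTCACCCG", "GATGATCATGTCGAACTTCT",
                 "CTGGTTATTTGTACAAGTAGCA", "CASGTGAARTGATAATCTCCSAC",
                 "TACCGATGTAGTTCTTGCC", "GACTTGATCCAGTTGGAGA",
                 "CACACCTAAAATGGACAGGA", "ATGCTAGCAARTACGTGATG",
                 "GGGAAACAATTTGTCGGTTA", "GCAGATCATTCGTAACAAGT",
                 "CCTCGATCGGRTTACCTTT"),
  length = c(464L, 480L, 498L, 468L, 444L, 498L, 489L, 495L, 494L, 469L,
             456L),
  multiplex_group = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L),
  stringsAsFactors = FALSE
)

# Engineered coding geometry: one CDS segment per locus, as 0-based
# insert offsets [cds_from, cds_to] and the number of coding bases of
# the transcript preceding the segment (fixes absolute codon numbering).
EXAMPLE_CDS_LAYOUT <- data.frame(
  locus_id = c("Rdl_Aeg", "Ace1", "DomainII", "DomainIIIExon35",
               "DomainI", "DomainIIS4", "DomainIIIExon36", "DomainIV",
               "DomainIIExon26", "DomainIIIExon33_34", "DomainIVS6"),
  cds_from = c(100L, 50L, 60L, 40L, 80L, 70L, 50L, 90L, 60L, 55L, 45L),
  cds_to = c(400L, 430L, 440L, 450L, 420L, 400L, 440L, 450L, 450L, 420L,
             410L),
  cds_offset = c(750L, 1141L, 2905L, 4419L, 1101L, 2640L, 4802L, 5202L,
                 2812L, 4413L, 5001L),
  stringsAsFactors = FALSE
)

# (locus, 0-based insert offset of codon first base, codon planted in
# the reference insert, absolute amino-acid number, resistance change,
# 0-based offset of the mutated nucleotide, ref and alt nucleotide)
EXAMPLE_KNOWN <- data.frame(
  locus_id = c("Rdl_Aeg", "Ace1", "DomainII", "DomainIIIExon35"),
  codon_off = c(235L, 250L, 200L, 220L),
  codon = c("GCA", "GGA", "GTA", "TTC"),
  aa_num = c(296L, 448L, 1016L, 1534L),
  ref_aa = c("A", "G", "V", "F"),
  alt_aa = c("S", "S", "G", "C"),
  label = c("A296S", "G119S (448 in Ae. aegypti)", "V1016G", "F1534C"),
  mut_rel = c(0L, 0L, 1L, 1L),   # offset of the changed base within codon
  alt_nt = c("T", "A", "G", "G"),
  stringsAsFactors = FALSE
)

resolve_iupac <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(b) IUPAC_CODES[[b]][1L], character(1)),
        collapse = "")
}

#' Built-in 11-amplicon demonstration panel
#'
#' Builds the three-gene (vgsc, ace-1, rdl) insecticide-resistance
#' amplicon panel with synthetic reference inserts: each insert is a
#' seeded random sequence of the declared length with the assay's primer
#' sequences grafted at the ends and known resistance codons planted at
#' literature-consistent coordinates. Deterministic: repeated calls
#' return identical panels.
#'
#' @return an `amp_panel` with 11 loci, CDS segments and 4 known
#'   resistance sites.
#' @examples
#' panel <- example_panel()
#' panel$loci[panel$loci$gene == "rdl", ]
#' @export
example_panel <- function() {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(104729L)  # fixture identity: fixed forever
  loci <- data.table::as.data.table(EXAMPLE_LOCI)
  loci$end <- loci$start + loci$length - 1L
  data.table::setcolorder(loci, c("locus_id", "gene", "chrom", "start",
                                  "end", "fwd_primer", "rev_primer",
                                  "length", "multiplex_group"))
  inserts <- character(nrow(loci))
  names(inserts) <- loci$locus_id
  for (i in seq_len(nrow(loci))) {
    row <- loci[i]
    fwd <- resolve_iupac(row$fwd_primer)
    rev3 <- revcomp(resolve_iupac(row$rev_primer))
    body_len <- row$length - nchar(fwd) - nchar(rev3)
    body <- paste(sample(c("A", "C", "G", "T"), body_len, replace = TRUE),
                  collapse = "")
    ins <- paste0(fwd, body, rev3)
    ks <- EXAMPLE_KNOWN[EXAMPLE_KNOWN$locus_id == row$locus_id, ]
    if (nrow(ks)) {
      substr(ins, ks$codon_off + 1L, ks$codon_off + 3L) <- ks$codon
    }
    inserts[[row$locus_id]] <- ins
  }
  lay <- merge(data.table::as.data.table(EXAMPLE_CDS_LAYOUT),
               loci[, c("locus_id", "start")], by = "locus_id", sort = FALSE)
  cds <- data.table::data.table(
    locus_id = lay$locus_id,
    cds_start = lay$start + lay$cds_from,
    cds_end = lay$start + lay$cds_to,
    strand = "+",
    frame = (3L - (lay$cds_offset %% 3L)) %% 3L,
    cds_offset = lay$cds_offset
  )
  data.table::setorder(cds, locus_id)
  kn <- merge(data.table::as.data.table(EXAMPLE_KNOWN),
              loci[, c("locus_id", "start")], by = "locus_id", sort = FALSE)
  known <- data.table::data.table(
    locus_id = kn$locus_id,
    pos = kn$start + kn$codon_off + kn$mut_rel,
    ref_aa = kn$ref_aa, alt_aa = kn$alt_aa, label = kn$label
  )
  data.table::setorder(known, locus_id)
  panel <- structure(list(loci = loci, inserts = inserts, cds = cds,
                          known_sites = known),
                     class = "amp_panel")
  validate_panel(panel)
  panel
}

# Deterministic barcode set: greedy selection of 6-mers with pairwise
# Hamming distance >= 3 from a seeded random stream.
make_barcodes <- function(n, seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  picked <- character(0)
  picked_m <- NULL
  while (length(picked) < n) {
    cand <- sample(c("A", "C", "G", "T"), BARCODE_LEN, replace = TRUE)
    if (is.null(picked_m) ||
        all(colSums(matrix(cand != t(picked_m), nrow = BARCODE_LEN)) >= 3L)) {
      picked <- c(picked, paste(cand, collapse = ""))
      picked_m <- rbind(picked_m, cand)
    }
  }
  picked
}

#' Built-in demonstration sample sheet
#'
#' One dual 6bp barcode combination per mosquito; samples are split
#' across pools in consecutive blocks, mirroring the published scheme of
#' 20 mosquitoes x 11 loci = 220 amplicons per pool.
#'
#' @param n_samples total mosquitoes (default 20).
#' @param n_pools number of sequencing pools (default 1).
#' @return a `sample_sheet`.
#' @export
example_sheet <- function(n_samples = 20L, n_pools = 1L) {
  fwd <- make_barcodes(n_samples, seed = 20221213L)
  rev <- make_barcodes(n_samples, seed = 48112L)
  pool <- rep(seq_len(n_pools), each = ceiling(n_samples / n_pools),
              length.out = n_samples)
  read_sample_sheet(data.frame(
    sample_id = sprintf("M%03d", seq_len(n_samples)),
    fwd_barcode = fwd, rev_barcode = rev,
    pool_id = sprintf("pool%d", pool),
    stringsAsFactors = FALSE
  ))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
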