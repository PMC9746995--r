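# Per-sample, per-amplicon variant calling: glocal alignment of trimmed
# reads to the reference insert, quality-filtered pileup, SNP/small
# indel calling and allele-ratio diploid genotyping.

#' Glocal alignment of a trimmed read to a reference insert
#'
#' The read is aligned end to end; reference end-gaps are free (global
#' in the read, local in the reference). Scoring: match +1, mismatch -1,
#' a gap of length L costs `gap_open + L * gap_extend`. Ties are broken
#' deterministically (smallest end position, diagonal-preferring
#' traceback).
#'
#' @param read A/C/G/T string, `nchar(read) <= nchar(insert_seq)`
#'   recommended (longer reads align with insertions).
#' @param insert_seq reference insert string.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list with `score`, `insert_start` (0-based offset of the
#'   first consumed reference base) and `cigar` (M/I/D runs; I consumes
#'   read only, D reference only).
#' @export
align_to_insert <- function(read, insert_seq, match = 1L, mismatch = -1L,
                            gap_open = -4L, gap_extend = -1L) {
  res <- glocal_align_cpp(toupper(read), toupper(insert_seq),
                          match, mismatch, gap_open, gap_extend)
  list(score = res$score, insert_start = res$ref_start, cigar = res$cigar)
}

# Align one (sample, locus) read group. Mate 1 (fwd_*) aligns directly;
# mate 2 is reverse-complemented (qualities reversed) first. Returns a
# data.table of alignment records keyed by the originating pair.
align_group <- function(group, insert_seq) {
  n <- nrow(group)
  rc2 <- revcomp(group$rev_seq)
  q2 <- vapply(strsplit(group$rev_qual, "", fixed = TRUE),
               function(ch) paste(rev(ch), collapse = ""), character(1))
  seqs <- c(group$fwd_seq, rc2)
  # amplicon reads are highly redundant: align each distinct sequence once
  uniq <- unique(seqs)
  hits <- lapply(uniq, align_to_insert, insert_seq = insert_seq)
  idx <- match(seqs, uniq)
  data.table::data.table(
    pair_id = rep(group$read_id, 2L),
    mate = rep(c(1L, 2L), each = n),
    insert_start = vapply(hits, `[[`, integer(1), "insert_start")[idx],
    cigar = vapply(hits, `[[`, character(1), "cigar")[idx],
    seq = seqs,
    qual = c(group$fwd_qual, q2))
}

parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  list(lens = lens, ops = ops)
}

# VCF-style left alignment of an indel given the insert sequence.
# pos0 is the 0-based offset of the first base of ref_str.
normalize_indel <- function(insert_seq, pos0, ref_str, alt_str) {
  repeat {
    nr <- nchar(ref_str); na <- nchar(alt_str)
    if (nr > 0L && na > 0L && (nr > 1L || na > 1L) &&
        substr(ref_str, nr, nr) == substr(alt_str, na, na)) {
      ref_str <- substr(ref_str, 1L, nr - 1L)
      alt_str <- substr(alt_str, 1L, na - 1L)
    } else if ((nchar(ref_str) == 0L || nchar(alt_str) == 0L) && pos0 > 0L) {
      b <- substr(insert_seq, pos0, pos0)
      ref_str <- paste0(b, ref_str)
      alt_str <- paste0(b, alt_str)
      pos0 <- pos0 - 1L
    } else break
  }
  list(pos0 = pos0, ref = ref_str, alt = alt_str)
}

#' Build a quality-filtered pileup from alignment records
#'
#' Each aligned base with phred `>= min_base_quality` increments its
#' allele's depth at its insert offset; lower-quality bases count only
#' toward the raw (spanning) depth. Overlapping mate bases at the same
#' offset are counted once, keeping the higher-quality observation.
#' Insertions and deletions are recorded as indel alleles at their
#' left-aligned anchor offset, keyed `"<ref>><alt>"` with one anchor
#' base (VCF convention).
#'
#' @param alignments data.table with columns `pair_id`, `insert_start`,
#'   `cigar`, `seq`, `qual` (as from the internal aligner).
#' @param insert_seq the reference insert.
#' @param cfg a `filter_config`.
#' @return an object of class `amp_pileup`: list with `ad` (data.table
#'   `insert_offset`, `allele`, `count`), `raw` (data.table
#'   `insert_offset`, `raw_depth`), `insert_seq` and `cfg`.
#' @export
build_pileup <- function(alignments, insert_seq, cfg = filter_config()) {
  insert_len <- nchar(insert_seq)
  empty <- function() {
    structure(list(
      ad = data.table::data.table(insert_offset = integer(),
                                  allele = character(), count = integer()),
      raw = data.table::data.table(insert_offset = integer(),
                                   raw_depth = integer()),
      insert_seq = insert_seq, cfg = cfg), class = "amp_pileup")
  }
  if (is.null(alignments) || nrow(alignments) == 0L) return(empty())

  simple <- grepl("^[0-9]+M$", alignments$cigar)
  obs <- vector("list", 2L)

  if (any(simple)) {
    al <- alignments[simple]
    lens <- nchar(al$seq)
    if (any(al$insert_start + lens > insert_len)) {
      stop("alignment extends beyond insert")
    }
    offs <- sequence(lens, from = al$insert_start)
    bases <- unlist(strsplit(al$seq, "", fixed = TRUE), use.names = FALSE)
    quals <- unlist(lapply(al$qual, function(q) as.integer(charToRaw(q)) - 33L),
                    use.names = FALSE)
    obs[[1L]] <- data.table::data.table(
      pair_id = rep(al$pair_id, lens), insert_offset = offs,
      allele = bases, qual = quals)
  }
  if (any(!simple)) {
    al <- alignments[!simple]
    rows <- vector("list", nrow(al))
    for (k in seq_len(nrow(al))) {
      cg <- parse_cigar(al$cigar[k])
      sch <- strsplit(al$seq[k], "", fixed = TRUE)[[1]]
      sq <- as.integer(charToRaw(al$qual[k])) - 33L
      p <- al$insert_start[k]; r <- 0L
      part <- list()
      for (u in seq_along(cg$ops)) {
        L <- cg$lens[u]
        if (cg$ops[u] == "M") {
          if (p + L > insert_len) stop("alignment extends beyond insert")
          part[[length(part) + 1L]] <- data.table::data.table(
            pair_id = al$pair_id[k], insert_offset = p + seq_len(L) - 1L,
            allele = sch[r + seq_len(L)], qual = sq[r + seq_len(L)])
          p <- p + L; r <- r + L
        } else if (cg$ops[u] == "I") {
          ins <- paste(sch[r + seq_len(L)], collapse = "")
          anchor <- p - 1L
          if (anchor >= 0L) {
            nz <- normalize_indel(insert_seq, anchor,
                                  substr(insert_seq, anchor + 1L, anchor + 1L),
                                  paste0(substr(insert_seq, anchor + 1L,
                                                anchor + 1L), ins))
            part[[length(part) + 1L]] <- data.table::data.table(
              pair_id = al$pair_id[k], insert_offset = nz$pos0,
              allele = paste0(nz$ref, ">", nz$alt),
              qual = min(sq[r + seq_len(L)]))
          }
          r <- r + L
        } else {  # D
          if (p + L > insert_len) stop("alignment extends beyond insert")
          anchor <- p - 1L
          if (anchor >= 0L) {
            nz <- normalize_indel(insert_seq, anchor,
                                  substr(insert_seq, anchor + 1L, anchor + L + 1L),
                                  substr(insert_seq, anchor + 1L, anchor + 1L))
            part[[length(part) + 1L]] <- data.table::data.table(
              pair_id = al$pair_id[k], insert_offset = nz$pos0,
              allele = paste0(nz$ref, ">", nz$alt),
              qual = if (r > 0L) sq[r] else max(sq))
          }
          p <- p + L
        }
      }
      rows[[k]] <- data.table::rbindlist(part)
    }
    obs[[2L]] <- data.table::rbindlist(rows)
  }
  ob <- data.table::rbindlist(obs[!vapply(obs, is.null, logical(1))])
  if (nrow(ob) == 0L) return(empty())

  is_indel <- grepl(">", ob$allele, fixed = TRUE)
  bases <- ob[!is_indel]
  indels <- ob[is_indel]
  # mate-overlap dedup: one base observation per (pair, offset), best
  # quality; one indel observation per (pair, anchor, allele)
  data.table::setorderv(bases, c("pair_id", "insert_offset", "qual"),
                        order = c(1L, 1L, -1L))
  bases <- unique(bases, by = c("pair_id", "insert_offset"))
  if (nrow(indels)) {
    data.table::setorderv(indels, c("pair_id", "insert_offset", "qual"),
                          order = c(1L, 1L, -1L))
    indels <- unique(indels, by = c("pair_id", "insert_offset", "allele"))
    # a read carrying an indel supports the indel allele at its anchor
    # column, not additionally the anchor reference base
    anchor_key <- paste(indels$pair_id, indels$insert_offset)
    bases <- bases[!paste(bases$pair_id, bases$insert_offset) %in% anchor_key]
  }
  ob <- rbind(bases, indels)

  raw <- ob[, list(raw_depth = .N), by = "insert_offset"]
  keep <- ob[ob$qual >= cfg$min_base_quality]
  ad <- keep[, list(count = .N), by = c("insert_offset", "allele")]
  data.table::setorderv(raw, "insert_offset")
  data.table::setorderv(ad, c("insert_offset", "allele"))
  structure(list(ad = ad[], raw = raw[], insert_seq = insert_seq, cfg = cfg),
            class = "amp_pileup")
}

#' Extract one pileup column
#' @param pileup an `amp_pileup`.
#' @param insert_offset 0-based offset.
#' @return list with `insert_offset`, `allele_depths` (named integer),
#'   `raw_depth` and `ref` (the insert base at the offset).
#' @export
pileup_column <- function(pileup, insert_offset) {
  idx <- which(pileup$ad$insert_offset == insert_offset)  # outside [: NSE-safe
  ad <- pileup$ad[idx, ]
  depths <- ad$count
  names(depths) <- ad$allele
  raw <- pileup$raw$raw_depth[pileup$raw$insert_offset == insert_offset]
  list(insert_offset = insert_offset,
       allele_depths = depths,
       raw_depth = if (length(raw)) raw else 0L,
       ref = substr(pileup$insert_seq, insert_offset + 1L, insert_offset + 1L))
}

#' Allele-ratio diploid genotyping of one pileup column
#'
#' If the quality-passing depth is below `min_depth` the genotype is
#' `missing`. Otherwise alleles with depth `>= min_allele_depth` are
#' considered; the top two by depth (reference first on ties) define the
#' allele ratio major/(major+minor) (1.0 when only one allele
#' qualifies). Calls at ratio `>= hom_ratio_threshold` are homozygous
#' for the major allele — the reassignment of borderline heterozygotes
#' with ratios in 0.8-1 that restores full replicate concordance — and
#' heterozygous otherwise.
#'
#' @param column a pileup column (see [pileup_column()]); must carry a
#'   `ref` element or `ref` must be supplied.
#' @param cfg a `filter_config`.
#' @param ref reference allele (defaults to `column$ref`).
#' @return list with `genotype` (`hom_ref`/`het`/`hom_alt`/`missing`),
#'   `depth` (quality-passing), `allele_ratio`, `major`, `minor`,
#'   `allele_depths`.
#' @export
genotype_site <- function(column, cfg = filter_config(), ref = column$ref) {
  depths <- column$allele_depths
  depth <- sum(depths)
  out <- list(genotype = "missing", depth = as.integer(depth),
              allele_ratio = NA_real_, major = NA_character_,
              minor = NA_character_, allele_depths = depths)
  if (depth < cfg$min_depth) return(out)
  qual <- depths[depths >= cfg$min_allele_depth]
  if (length(qual) == 0L) return(out)
  # order by depth desc, reference first on ties, then alphabetical
  is_ref <- names(qual) == ref
  ord <- order(-qual, -is_ref, names(qual))
  qual <- qual[ord]
  if (length(qual) == 1L) {
    major <- names(qual)[1L]
    ratio <- 1.0
    minor <- NA_character_
  } else {
    major <- names(qual)[1L]
    minor <- names(qual)[2L]
    ratio <- unname(qual[1L] / (qual[1L] + qual[2L]))
  }
  if (ratio >= cfg$hom_ratio_threshold) {
    gt <- if (major == ref) "hom_ref" else "hom_alt"
  } else {
    gt <- "het"
  }
  out$genotype <- gt
  out$allele_ratio <- ratio
  out$major <- major
  out$minor <- minor
  out
}

# split an allele key into VCF-style (ref, alt) strings given the
# reference base at the offset
allele_to_ref_alt <- function(allele, ref_base) {
  if (grepl(">", allele, fixed = TRUE)) {
    parts <- strsplit(allele, ">", fixed = TRUE)[[1]]
    list(ref = parts[1L], alt = parts[2L])
  } else {
    list(ref = ref_base, alt = allele)
  }
}

# genotype one sample's pileup at a set of offsets; returns call rows
genotype_offsets <- function(pileup, offsets, panel, locus_id, sample_id,
                             cfg) {
  idx <- which(panel$loci$locus_id == locus_id)  # outside [: NSE-safe
  row <- panel$loci[idx, ]
  out <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    off <- offsets[k]
    col <- pileup_column(pileup, off)
    call <- genotype_site(col, cfg)
    ref_base <- col$ref
    # site alt: the top qualifying non-reference allele
    depths <- col$allele_depths
    nonref <- depths[names(depths) != ref_base & depths >= cfg$min_allele_depth]
    alt_key <- if (length(nonref)) names(nonref)[which.max(nonref)] else NA_character_
    if (!is.na(alt_key)) {
      ra <- allele_to_ref_alt(alt_key, ref_base)
      site_ref <- ra$ref; site_alt <- ra$alt
    } else {
      site_ref <- ref_base; site_alt <- NA_character_
    }
    ad_ref <- if (ref_base %in% names(depths)) depths[[ref_base]] else 0L
    ad_alt <- if (!is.na(alt_key) && alt_key %in% names(depths))
      depths[[alt_key]] else 0L
    out[[k]] <- data.table::data.table(
      sample_id = sample_id, locus_id = locus_id, chrom = row$chrom,
      pos = offset_to_genomic(panel, locus_id, off),
      insert_offset = off, ref = site_ref, alt = site_alt,
      genotype = call$genotype, depth = call$depth,
      ad_ref = as.integer(ad_ref), ad_alt = as.integer(ad_alt),
      allele_ratio = call$allele_ratio)
  }
  data.table::rbindlist(out)
}

# offsets in a pileup where some non-reference allele passes
# min_allele_depth
variant_offsets <- function(pileup, cfg) {
  ad <- pileup$ad
  if (nrow(ad) == 0L) return(integer(0))
  ref_at <- substr(rep(pileup$insert_seq, nrow(ad)), ad$insert_offset + 1L,
                   ad$insert_offset + 1L)
  hit <- ad$allele != ref_at & ad$count >= cfg$min_allele_depth
  sort(unique(ad$insert_offset[hit]))
}

# Align every (sample, locus) group and build pileups.
# Returns a nested list pileups[[sample_id]][[locus_id]].
sample_pileups <- function(groups, panel, cfg = filter_config()) {
  bad <- setdiff(unique(groups$locus_id), panel$loci$locus_id)
  if (length(bad)) stop("unknown locus: ", paste(bad, collapse = ", "))
  out <- list()
  keys <- unique(groups[, c("sample_id", "locus_id")])
  for (i in seq_len(nrow(keys))) {
    sid <- keys$sample_id[i]; lid <- keys$locus_id[i]
    g <- groups[groups$sample_id == sid & groups$locus_id == lid, ]
    aln <- align_group(g, panel$inserts[[lid]])
    out[[sid]][[lid]] <- build_pileup(aln, panel$inserts[[lid]], cfg)
  }
  out
}

#' Call variants and known-site genotypes for one sample
#'
#' Emits a genotype call at every site where a non-reference allele
#' passes `min_allele_depth`, plus calls at the panel's known resistance
#' sites regardless of variation, so wild-type status at those positions
#' is always reported.
#'
#' @param groups demultiplexed, trimmed read groups for one sample (the
#'   [demultiplex()] `groups` table filtered to one `sample_id`).
#' @param panel an `amp_panel`.
#' @param cfg a `filter_config`.
#' @return data.table of per-site calls: `sample_id`, `locus_id`,
#'   `chrom`, `pos`, `insert_offset`, `ref`, `alt` (NA at monomorphic
#'   known sites), `genotype`, `depth`, `ad_ref`, `ad_alt`,
#'   `allele_ratio`.
#' @export
call_sample_variants <- function(groups, panel, cfg = filter_config()) {
  sid <- unique(groups$sample_id)
  if (length(sid) != 1L) stop("groups must contain exactly one sample")
  pls <- sample_pileups(groups, panel, cfg)[[sid]]
  out <- list()
  loci <- union(names(pls),
                unique(panel$known_sites$locus_id))
  for (lid in loci) {
    pl <- pls[[lid]]
    if (is.null(pl)) {
      pl <- build_pileup(NULL, panel$inserts[[lid]], cfg)
    }
    offs <- variant_offsets(pl, cfg)
    ks <- panel$known_sites[panel$known_sites$locus_id == lid, ]
    if (nrow(ks)) {
      offs <- sort(union(offs, genomic_to_offset(panel, lid, ks$pos)))
    }
    if (length(offs)) {
      out[[lid]] <- genotype_offsets(pl, offs, panel, lid, sid, cfg)
    }
  }
  if (length(out) == 0L) {
    return(data.table::data.table(
      sample_id = character(), locus_id = character(), chrom = character(),
      pos = integer(), insert_offset = integer(), ref = character(),
      alt = character(), genotype = character(), depth = integer(),
      ad_ref = integer(), ad_alt = integer(), allele_ratio = numeric()))
  }
  data.table::rbindlist(out)
}
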