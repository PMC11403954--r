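#' Estimate terminal deamination damage profiles
#'
#' Exact mismatch-count estimator: for each read position `p` counted from
#' the 5' end, `rate = (C->T mismatches at p) / (reference-C opportunities
#' at p)`, and symmetrically G->A counted from the 3' end.  Reads are
#' assumed to align to the reference exactly at their stated start (the
#' fixture guarantees this; there are no indels).
#'
#' @param reads data.frame `sample_id`, `contig`, `start` (0-based), `seq`;
#'   all reads must have equal length.
#' @param reference named character vector of contig sequences.
#' @return data.frame `sample_id`, `end` (`"five_prime"`/`"three_prime"`),
#'   `position` (1-based from that end), `mismatches`, `opportunities`,
#'   `rate` (`NA` where there are no opportunities).
#' @export
estimate_damage_profile <- function(reads, reference) {
  empty <- data.frame(sample_id = character(0), end = character(0),
                      position = integer(0), mismatches = integer(0),
                      opportunities = integer(0), rate = numeric(0))
  if (nrow(reads) == 0L) return(empty)
  L <- unique(nchar(reads$seq))
  if (length(L) != 1L) stop("reads must all have the same length")
  res <- list()
  for (sid in unique(reads$sample_id)) {
    r <- reads[reads$sample_id == sid, , drop = FALSE]
    refseq <- substring(reference[r$contig], r$start + 1L, r$start + L)
    refM <- seqs_to_matrix(refseq, L)
    readM <- seqs_to_matrix(r$seq, L)
    ct_mm <- ct_opp <- ga_mm <- ga_opp <- integer(L)
    for (j in seq_len(L)) {
      isC <- refM[, j] == "C"; isG <- refM[, j] == "G"
      ct_opp[j] <- sum(isC)
      ct_mm[j] <- sum(isC & readM[, j] == "T")
      ga_opp[j] <- sum(isG)
      ga_mm[j] <- sum(isG & readM[, j] == "A")
    }
    res[[length(res) + 1L]] <- data.frame(
      sample_id = sid,
      end = rep(c("five_prime", "three_prime"), each = L),
      position = c(seq_len(L), rev(seq_len(L))),
      mismatches = c(ct_mm, ga_mm),
      opportunities = c(ct_opp, ga_opp),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$sample_id, out$end == "three_prime", out$position), ]
  out$rate <- ifelse(out$opportunities > 0,
                     out$mismatches / out$opportunities, NA_real_)
  rownames(out) <- NULL
  out
}

# is an allele pair the signature a deamination artefact could produce?
is_damage_pair <- function(a, b) {
  (a == "C" & b == "T") | (a == "T" & b == "C") |
    (a == "G" & b == "A") | (a == "A" & b == "G")
}

#' Minor-base proportion rule for a heterozygous call
#'
#' The read support of the less-supported genotype allele divided by the
#' combined support of both genotype alleles.  A call is provisionally a
#' true heterozygote only when the proportion exceeds `threshold`
#' (strictly); at or below the threshold it is a potential false positive
#' pending the read-position check.  Reads supporting neither genotype
#' allele are reported but excluded from the ratio.
#'
#' @param counts named numeric vector of per-base read counts
#'   (names `A`, `C`, `G`, `T`).
#' @param alleles character vector of the two genotype alleles.
#' @param threshold minor-base proportion threshold (default 0.30).
#' @return list: `minor_allele`, `minor_count`, `major_count`,
#'   `minor_base_proportion`, `third_base_count`, `is_damage_type`,
#'   `verdict` (`"true_het"` / `"potential_false_positive"`).
#' @export
validate_heterozygote <- function(counts, alleles, threshold = 0.30) {
  stopifnot(length(alleles) == 2L, all(alleles %in% DNA_BASES))
  c2 <- as.numeric(counts[alleles])
  if (sum(c2) == 0)
    stop("zero read depth on both genotype alleles (",
         paste(alleles, collapse = "/"), ")")
  minor_i <- which.min(c2)
  prop <- c2[minor_i] / sum(c2)
  list(minor_allele = alleles[minor_i],
       minor_count = c2[minor_i],
       major_count = c2[-minor_i],
       minor_base_proportion = prop,
       third_base_count = sum(as.numeric(counts[DNA_BASES])) - sum(c2),
       is_damage_type = unname(is_damage_pair(alleles[1], alleles[2])),
       verdict = if (prop > threshold) "true_het" else
         "potential_false_positive")
}

#' Read-position check for a flagged heterozygous call
#'
#' Of the reads supporting the minor allele at a site, the fraction whose
#' variant base lies within `k` bases of either read end.  Deamination
#' artefacts concentrate at read ends, so a flagged call whose minor-allele
#' support sits mid-read is rescued to a true heterozygote when the
#' terminal fraction is at most `cutoff` (inclusive).
#'
#' @param reads data.frame `sample_id`, `contig`, `start`, `seq`.
#' @param sample_id,contig,pos the call to check (`pos` 0-based).
#' @param minor_allele the minor base.
#' @param k terminal window (bp, default 5).
#' @param cutoff maximum terminal fraction compatible with a true
#'   heterozygote (default 0.5).
#' @return list: `n_minor_reads`, `terminal_minor_fraction` (`NA` when no
#'   minor-allele reads are found), `rescued`.
#' @export
minor_allele_position_check <- function(reads, sample_id, contig, pos,
                                        minor_allele, k = 5L, cutoff = 0.5) {
  rl <- nchar(reads$seq)
  sel <- reads$sample_id == sample_id & reads$contig == contig &
    reads$start <= pos & pos < reads$start + rl
  off <- pos - reads$start[sel] + 1L                  # 1-based in read
  base <- substr(reads$seq[sel], off, off)
  minor <- base == minor_allele
  if (!any(minor))
    return(list(n_minor_reads = 0L, terminal_minor_fraction = NA_real_,
                rescued = FALSE))
  dist_end <- pmin(off[minor], rl[sel][minor] - off[minor] + 1L)
  frac <- mean(dist_end <= k)
  list(n_minor_reads = sum(minor), terminal_minor_fraction = frac,
       rescued = frac <= cutoff)
}

#' Validate every ancient heterozygous call
#'
#' Scans the (depth-masked) genotype matrix for heterozygous calls in
#' ancient samples, applies the minor-base-proportion rule from the base
#' counts and, for damage-type pairs flagged by the proportion rule, the
#' read-position rescue.  The rescue only ever flips a potential false
#' positive to a true heterozygote, never the reverse.
#'
#' @param geno a depth-masked [genotype_set()].
#' @param base_counts data.frame from [count_bases_from_reads()] /
#'   [read_base_counts()].
#' @param reads optional read table for the position check (without it,
#'   flagged damage-type calls keep their provisional verdict).
#' @param threshold minor-base proportion threshold (default 0.30).
#' @param k,cutoff position-check parameters.
#' @return data.frame, one row per ancient heterozygous call: site, sample,
#'   alleles, proportion, damage-type flag, position-check fields,
#'   provisional and final verdicts.
#' @export
validate_ancient_heterozygotes <- function(geno, base_counts, reads = NULL,
                                           threshold = 0.30, k = 5L,
                                           cutoff = 0.5) {
  anc <- which(geno$samples$era == "ancient")
  rows <- list()
  for (j in anc) {
    sid <- geno$samples$sample_id[j]
    for (s in seq_len(nrow(geno$sites))) {
      g <- geno$gt[s, j]
      if (is.na(g)) next
      pair <- strsplit(g, "/", fixed = TRUE)[[1]]
      if (pair[1] == pair[2]) next
      cn <- geno$sites$contig[s]; pos <- geno$sites$pos[s]
      bc <- base_counts[base_counts$contig == cn & base_counts$pos == pos &
                          base_counts$sample_id == sid, , drop = FALSE]
      if (nrow(bc) == 0L)
        stop(sprintf("no base counts for het call %s:%d in %s",
                     cn, pos + 1L, sid))
      counts <- c(A = bc$nA[1], C = bc$nC[1], G = bc$nG[1], T = bc$nT[1])
      v <- validate_heterozygote(counts, pair, threshold)
      pc <- list(n_minor_reads = NA_integer_,
                 terminal_minor_fraction = NA_real_, rescued = NA)
      final <- v$verdict
      if (v$verdict == "potential_false_positive" && v$is_damage_type &&
          !is.null(reads)) {
        pc <- minor_allele_position_check(reads, sid, cn, pos,
                                          v$minor_allele, k, cutoff)
        if (isTRUE(pc$rescued)) final <- "true_het"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cn, pos = pos, sample_id = sid, genotype = g,
        minor_allele = v$minor_allele, minor_count = v$minor_count,
        major_count = v$major_count,
        minor_base_proportion = v$minor_base_proportion,
        third_base_count = v$third_base_count,
        is_damage_type = v$is_damage_type,
        proportion_verdict = v$verdict,
        n_minor_reads = pc$n_minor_reads,
        terminal_minor_fraction = pc$terminal_minor_fraction,
        rescued = isTRUE(pc$rescued),
        verdict = final, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(contig = character(0), pos = integer(0),
                      sample_id = character(0), genotype = character(0),
                      minor_allele = character(0), minor_count = numeric(0),
                      major_count = numeric(0),
                      minor_base_proportion = numeric(0),
                      third_base_count = numeric(0),
                      is_damage_type = logical(0),
                      proportion_verdict = character(0),
                      n_minor_reads = integer(0),
                      terminal_minor_fraction = numeric(0),
                      rescued = logical(0), verdict = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Restrict heterozygote validations to damage-type pairs
#'
#' @param het_validations output of [validate_ancient_heterozygotes()].
#' @return list with `table` (damage-type rows only) and `verdict_counts`.
#' @export
flag_damage_candidates <- function(het_validations) {
  tab <- het_validations[het_validations$is_damage_type, , drop = FALSE]
  list(table = tab,
       verdict_counts = c(
         true_het = sum(tab$verdict == "true_het"),
         potential_false_positive =
           sum(tab$verdict == "potential_false_positive")))
}
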