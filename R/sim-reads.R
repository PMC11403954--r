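# char matrix <-> string helpers for fixed-length reads
seqs_to_matrix <- function(seqs, L) {
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         ncol = L, byrow = TRUE)
}
matrix_to_seqs <- function(M) {
  do.call(paste0, lapply(seq_len(ncol(M)), function(j) M[, j]))
}

# Apply terminal deamination to reads that are exact reference copies:
# C->T from the 5' end and G->A from the 3' end, with probability
# rate * decay^(position - 1) at each position counted from its end.
apply_deamination <- function(seqs, rate, decay, L) {
  if (length(seqs) == 0L || rate == 0) return(seqs)
  M <- seqs_to_matrix(seqs, L)
  out <- M
  for (j in seq_len(L)) {
    p5 <- rate * decay^(j - 1L)
    p3 <- rate * decay^(L - j)
    if (p5 > 0) {
      hit <- M[, j] == "C" & runif(nrow(M)) < p5
      out[hit, j] <- "T"
    }
    if (p3 > 0) {
      hit <- M[, j] == "G" & runif(nrow(M)) < p3
      out[hit, j] <- "A"
    }
  }
  matrix_to_seqs(out)
}

# uniform sequencing error: each base replaced by a random other base
apply_seq_error <- function(seqs, rate, L) {
  if (length(seqs) == 0L || rate == 0) return(seqs)
  M <- seqs_to_matrix(seqs, L)
  hit <- matrix(runif(length(M)) < rate, nrow(M), ncol(M))
  if (any(hit)) {
    idx <- which(hit)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    cur <- match(M[idx], DNA_BASES)
    M[idx] <- DNA_BASES[(cur - 1L + shift) %% 4L + 1L]
  }
  matrix_to_seqs(M)
}

#' Heterozygote read plan implied by a truth table
#'
#' One row per planted ancient heterozygous site (the `fixed_post` sites):
#' which ancient sample is heterozygous, the major (derived) and minor
#' (ancestral) allele, and the exact read counts realising the target
#' minor-base proportion.
#'
#' @param truth truth table from [plant_site_truth()].
#' @param spec a [cohort_spec()].
#' @return data.frame `sample_id`, `gene`, `contig`, `pos`, `major`,
#'   `minor`, `n_major`, `n_minor`, `target_prop`.
#' @export
het_read_plan <- function(truth, spec) {
  rows <- truth[truth$class == "fixed_post" & !is.na(truth$het_sample), ,
                drop = FALSE]
  if (nrow(rows) == 0L || spec$n_ancient == 0L)
    return(data.frame(sample_id = character(0), gene = character(0),
                      contig = character(0), pos = integer(0),
                      major = character(0), minor = character(0),
                      n_major = integer(0), n_minor = integer(0),
                      target_prop = numeric(0)))
  anc_ids <- sprintf("ANC_%02d", seq_len(spec$n_ancient))
  idx <- (rows$het_sample - 1L) %% spec$n_ancient + 1L
  n_minor <- as.integer(round(rows$het_depth * rows$het_minor_prop))
  data.frame(sample_id = anc_ids[idx], gene = rows$gene,
             contig = rows$contig, pos = rows$pos,
             major = rows$derived, minor = rows$ancestral,
             n_major = rows$het_depth - n_minor, n_minor = n_minor,
             target_prop = rows$het_minor_prop, stringsAsFactors = FALSE)
}

#' Simulate ancient reads with terminal deamination
#'
#' Per ancient sample, draws `reads_per_ancient` background reads uniformly
#' over the reference (length-weighted across contigs), applies terminal
#' deamination at the sample's damage rate with geometric decay inward, and
#' adds clean reads realising the planted heterozygous sites: minor-allele
#' reads carry the variant mid-read (at least 20 bp from either end) and
#' major-allele reads are placed uniformly.  A sample's background reads
#' never overlap its own planted heterozygous sites, so the emitted base
#' counts reproduce the planted minor-base proportions exactly.
#'
#' @param truth truth table from [plant_site_truth()].
#' @param reference named character vector of contig sequences.
#' @param spec a [cohort_spec()].
#' @param seed optional integer seed.
#' @return list with `reads` (data.frame `sample_id`, `contig`, `start`
#'   0-based, `seq`) and `het_plan` (see [het_read_plan()]).
#' @export
simulate_ancient_reads <- function(truth, reference, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- spec$read_length
  if (any(nchar(reference) < L)) stop("contig shorter than read length")
  plan <- het_read_plan(truth, spec)
  anc_ids <- sprintf("ANC_%02d", seq_len(spec$n_ancient))
  contig_len <- nchar(reference)
  out <- list()
  for (a in seq_len(spec$n_ancient)) {
    sid <- anc_ids[a]
    rate <- spec$damage_rate_per_ancient[a]
    # background reads
    n <- spec$reads_per_ancient
    w <- contig_len - L + 1
    ctg <- sample(names(reference), n, replace = TRUE, prob = w / sum(w))
    start <- integer(n)
    for (cn in unique(ctg)) {
      sel <- ctg == cn
      start[sel] <- sample.int(w[[cn]], sum(sel), replace = TRUE) - 1L
    }
    # a sample's background reads avoid its own het sites
    own <- plan[plan$sample_id == sid, , drop = FALSE]
    keep <- rep(TRUE, n)
    for (h in seq_len(nrow(own))) {
      keep <- keep & !(ctg == own$contig[h] &
                         start > own$pos[h] - L & start <= own$pos[h])
    }
    ctg <- ctg[keep]; start <- start[keep]
    seqs <- substring(reference[ctg], start + 1L, start + L)
    seqs <- apply_deamination(seqs, rate, spec$damage_decay, L)
    seqs <- apply_seq_error(seqs, spec$seq_error_rate, L)
    bg <- data.frame(sample_id = sid, contig = ctg, start = start,
                     seq = seqs, stringsAsFactors = FALSE)
    # het-site reads (no damage: planted proportions are exact)
    het_reads <- list()
    for (h in seq_len(nrow(own))) {
      pos <- own$pos[h]; cn <- own$contig[h]
      mk <- function(k, allele, offsets) {
        if (k == 0L) return(NULL)
        off <- sample(offsets, k, replace = TRUE)
        st <- pos - off
        st <- pmin(pmax(st, 0L), contig_len[[cn]] - L)
        off <- pos - st
        sq <- substring(reference[[cn]], st + 1L, st + L)
        substr(sq, off + 1L, off + 1L) <- allele
        data.frame(sample_id = sid, contig = cn, start = st, seq = sq,
                   stringsAsFactors = FALSE)
      }
      het_reads[[length(het_reads) + 1L]] <-
        rbind(mk(own$n_minor[h], own$minor[h], 20:(L - 21L)),
              mk(own$n_major[h], own$major[h], 0:(L - 1L)))
    }
    out[[length(out) + 1L]] <- do.call(rbind, c(list(bg), het_reads))
  }
  reads <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), contig = character(0),
               start = integer(0), seq = character(0))
  rownames(reads) <- NULL
  list(reads = reads, het_plan = plan)
}

#' Per-site base counts from reads
#'
#' Recounts, for every requested site and every sample present in `reads`,
#' how many reads support each base at that position.
#'
#' @param reads data.frame `sample_id`, `contig`, `start` (0-based), `seq`.
#' @param sites data.frame with columns `contig`, `pos` (0-based).
#' @return data.frame `contig`, `pos`, `sample_id`, `nA`, `nC`, `nG`, `nT`.
#' @export
count_bases_from_reads <- function(reads, sites) {
  samples <- unique(reads$sample_id)
  rows <- vector("list", nrow(sites) * length(samples))
  k <- 0L
  rl <- nchar(reads$seq)
  for (sid in samples) {
    rsel <- reads$sample_id == sid
    for (i in seq_len(nrow(sites))) {
      pos <- sites$pos[i]; cn <- sites$contig[i]
      sel <- rsel & reads$contig == cn & reads$start <= pos &
        pos < reads$start + rl
      bases <- substr(reads$seq[sel], pos - reads$start[sel] + 1L,
                      pos - reads$start[sel] + 1L)
      tab <- table(factor(bases, levels = DNA_BASES))
      k <- k + 1L
      rows[[k]] <- data.frame(contig = cn, pos = pos, sample_id = sid,
                              nA = as.integer(tab[["A"]]),
                              nC = as.integer(tab[["C"]]),
                              nG = as.integer(tab[["G"]]),
                              nT = as.integer(tab[["T"]]),
                              stringsAsFactors = FALSE)
    }
  }
  res <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(contig = character(0), pos = integer(0),
               sample_id = character(0), nA = integer(0), nC = integer(0),
               nG = integer(0), nT = integer(0))
  rownames(res) <- NULL
  res
}
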