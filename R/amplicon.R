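# Read handling, barcode demultiplexing and read-to-panel alignment.
# Alignment is Smith-Waterman via Biostrings::pairwiseAlignment with fixed,
# documented scores (match +2, mismatch -4, gap open -4, gap extend -2).

aln_scores <- function() list(match = 2, mismatch = -4,
                              gap_open = 4, gap_extend = 2)

sub_matrix <- function() {
  s <- aln_scores()
  Biostrings::nucleotideSubstitutionMatrix(match = s$match,
                                           mismatch = s$mismatch)
}

#' Read and write FASTQ (Phred+33)
#'
#' Thin wrappers over Biostrings FASTQ support returning the package's
#' plain read table: columns `read_id`, `bases`, `quals`. Only Phred+33 is
#' accepted; a quality character outside the printable Phred+33 range is an
#' error, never a guess at another encoding.
#'
#' @param path FASTQ path.
#' @return A data.frame of class `read_set`.
#' @export
read_fastq <- function(path) {
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  reads <- data.frame(read_id = names(qs),
                      bases = as.character(qs),
                      quals = as.character(Biostrings::quality(qs)),
                      stringsAsFactors = FALSE)
  bad <- vapply(reads$quals, function(q) {
    r <- utf8ToInt(q); any(r < 33L | r > 126L)
  }, logical(1))
  if (any(bad))
    stop("quality characters outside the Phred+33 range in read(s): ",
         paste(utils::head(reads$read_id[bad], 3), collapse = ","))
  class(reads) <- c("read_set", "data.frame")
  reads
}

#' @rdname read_fastq
#' @param reads A `read_set` data.frame.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quals))
  invisible(path)
}

#' Mean-quality read filter
#'
#' Keeps reads whose mean per-base Phred quality is at least `min_mean_q`
#' (the platform's read-level pass filter convention; bases are not
#' individually masked). Malformed records — length mismatch between bases
#' and qualities, or symbols outside ACGTN — are rejected per read with a
#' logged reason, available as `attr(result, "rejected")`.
#'
#' @param reads A `read_set` data.frame.
#' @param min_mean_q Minimum mean Phred quality (default 10).
#' @return The passing subset of `reads`; rejected reads (with reasons) in
#'   the `"rejected"` attribute.
#' @export
quality_filter <- function(reads, min_mean_q = 10) {
  if (nrow(reads) == 0L) {
    attr(reads, "rejected") <- data.frame(read_id = character(0),
                                          reason = character(0))
    return(reads)
  }
  reason <- rep(NA_character_, nrow(reads))
  len_ok <- nchar(reads$bases) == nchar(reads$quals)
  reason[!len_ok] <- "bases/quality length mismatch"
  alpha_ok <- !grepl("[^ACGTN]", reads$bases)
  reason[len_ok & !alpha_ok] <- "non-ACGTN symbol"
  meanq <- rep(NA_real_, nrow(reads))
  ok <- len_ok & alpha_ok
  meanq[ok] <- vapply(reads$quals[ok],
                      function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                      USE.NAMES = FALSE)
  reason[ok & meanq < min_mean_q] <- sprintf("mean quality < %g", min_mean_q)
  keep <- is.na(reason)
  out <- reads[keep, , drop = FALSE]
  attr(out, "rejected") <- data.frame(read_id = reads$read_id[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

# k-mer lookup table: kmer string -> unique integer ids (environment hash)
kmer_env <- function(seqs, ids, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    n <- nchar(s)
    if (n < k) next
    for (p in 1:(n - k + 1L)) {
      km <- substr(s, p, p + k - 1L)
      env[[km]] <- union(env[[km]], ids[i])
    }
  }
  env
}

kmer_lookup <- function(env, s, k, stride) {
  n <- nchar(s)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (p in seq(1L, n - k + 1L, by = stride)) {
    v <- env[[substr(s, p, p + k - 1L)]]
    if (!is.null(v)) hits <- c(hits, v)
  }
  unique(hits)
}

# verify barcode vs window by local alignment; returns logical pass vector
barcode_end_pass <- function(windows, barcode_seq, min_match_length,
                             min_identity) {
  if (!length(windows)) return(logical(0))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(windows), Biostrings::DNAString(barcode_seq),
    type = "local", substitutionMatrix = sub_matrix(),
    gapOpening = aln_scores()$gap_open, gapExtension = aln_scores()$gap_extend)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  ident <- Biostrings::nmatch(aln) / cols
  cols > min_match_length & ident > min_identity
}

#' Demultiplex reads by double-ended barcode match
#'
#' A read is assigned to a barcode when a local alignment of the barcode
#' region against each read end has aligned length greater than
#' `min_match_length` bases and identity greater than `min_identity` —
#' at both ends when `require_both_ends` (the default). Either barcode
#' orientation is accepted at either end (reads may come off either
#' strand). Reads matching zero or two or more barcodes go to `unassigned`.
#'
#' A k-mer prescreen (exact 12-mers sampled along each end window) selects
#' candidate barcodes before alignment; candidates are then verified by the
#' alignment rule above, so the prescreen only affects speed.
#'
#' @param reads A `read_set` data.frame.
#' @param barcodes Data.frame with columns `barcode_id`, `sequence`
#'   (pairwise distinct).
#' @param min_match_length Minimum aligned length in bases (default 37).
#' @param min_identity Minimum alignment identity (default 0.95).
#' @param require_both_ends Require a match at both read ends (default TRUE).
#' @param end_window Bases examined at each read end (default: longest
#'   barcode + 20).
#' @return A list with `assigned` (named list: barcode_id -> `read_set`)
#'   and `unassigned` (`read_set`).
#' @export
demultiplex <- function(reads, barcodes, min_match_length = 37L,
                        min_identity = 0.95, require_both_ends = TRUE,
                        end_window = NULL) {
  stopifnot(!anyDuplicated(barcodes$sequence), !anyDuplicated(barcodes$barcode_id))
  nb <- nrow(barcodes)
  n <- nrow(reads)
  empty_set <- function() {
    x <- reads[0, , drop = FALSE]; class(x) <- c("read_set", "data.frame"); x
  }
  if (n == 0L)
    return(list(assigned = stats::setNames(
      replicate(nb, empty_set(), simplify = FALSE), barcodes$barcode_id),
      unassigned = empty_set()))
  if (is.null(end_window)) end_window <- max(nchar(barcodes$sequence)) + 20L
  k <- 12L; stride <- 4L
  bc_fwd <- barcodes$sequence
  bc_rev <- revcomp(bc_fwd)
  # candidate ids encode orientation: 1..nb forward, nb+1..2nb reverse
  env <- kmer_env(c(bc_fwd, bc_rev), seq_len(2L * nb), k)

  len <- nchar(reads$bases)
  w <- pmin(end_window, len)
  front <- substr(reads$bases, 1L, w)
  back <- substr(reads$bases, len - w + 1L, len)

  cand_front <- lapply(front, kmer_lookup, env = env, k = k, stride = stride)
  cand_back <- lapply(back, kmer_lookup, env = env, k = k, stride = stride)

  # verify candidates end-by-end in the orientation the k-mer hit suggests;
  # an exact full-barcode substring match passes without alignment
  pass_front <- matrix(FALSE, n, nb)
  pass_back <- matrix(FALSE, n, nb)
  verify <- function(windows, bc_seq) {
    out <- grepl(bc_seq, windows, fixed = TRUE)
    if (nchar(bc_seq) <= min_match_length) out[] <- FALSE  # exact too short
    todo <- which(!out)
    if (length(todo))
      out[todo] <- barcode_end_pass(windows[todo], bc_seq,
                                    min_match_length, min_identity)
    out
  }
  invert <- function(cand) {
    reps <- lengths(cand)
    split(rep(seq_len(n), reps), unlist(cand))
  }
  by_bo_front <- invert(cand_front)
  by_bo_back <- invert(cand_back)
  for (bo_chr in union(names(by_bo_front), names(by_bo_back))) {
    bo <- as.integer(bo_chr)
    b <- if (bo <= nb) bo else bo - nb
    bc_seq <- if (bo <= nb) bc_fwd[b] else bc_rev[b]
    fi <- by_bo_front[[bo_chr]]
    fi <- fi[!pass_front[fi, b]]
    if (length(fi)) pass_front[fi, b] <- verify(front[fi], bc_seq)
    bi <- by_bo_back[[bo_chr]]
    bi <- bi[!pass_back[bi, b]]
    if (length(bi)) pass_back[bi, b] <- verify(back[bi], bc_seq)
  }
  pass <- if (require_both_ends) pass_front & pass_back
          else pass_front | pass_back
  n_match <- rowSums(pass)
  assigned_idx <- ifelse(n_match == 1L, max.col(pass, ties.method = "first"),
                         NA_integer_)
  assigned <- stats::setNames(vector("list", nb), barcodes$barcode_id)
  for (b in seq_len(nb)) {
    x <- reads[which(assigned_idx == b), , drop = FALSE]
    class(x) <- c("read_set", "data.frame")
    assigned[[b]] <- x
  }
  un <- reads[is.na(assigned_idx), , drop = FALSE]
  class(un) <- c("read_set", "data.frame")
  list(assigned = assigned, unassigned = un)
}

aln_to_row <- function(aln, read_id, ref_name, strand, read_len,
                       read_bases) {
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  data.frame(
    read_id = read_id, ref = ref_name, strand = strand,
    score = Biostrings::score(aln),
    identity = Biostrings::nmatch(aln) / cols,
    ref_start = BiocGenerics::start(Biostrings::subject(aln)),
    ref_end = BiocGenerics::end(Biostrings::subject(aln)),
    read_start = BiocGenerics::start(Biostrings::pattern(aln)),
    read_end = BiocGenerics::end(Biostrings::pattern(aln)),
    aligned = as.character(Biostrings::aligned(aln)),
    read_bases = read_bases,
    read_len = read_len,
    stringsAsFactors = FALSE)
}

#' Align one read against the whole panel
#'
#' Best-scoring Smith-Waterman local alignment of the read (both strands)
#' against every panel amplicon, under fixed scores (match +2, mismatch -4,
#' gap open -4, gap extend -2). The read is reverse-complemented before
#' aligning the minus strand, so the returned `aligned` string is always in
#' reference sense coordinates (deletions as `-`, padded with `-` outside
#' the aligned interval to the full reference length). Alignments scoring
#' below `min_score_frac * read length * match score` are reported
#' unaligned.
#'
#' @param bases Read sequence (character scalar).
#' @param panel A `reference_panel`.
#' @param read_id Identifier carried into the result.
#' @param min_score_frac Score floor as a fraction of the perfect-match
#'   score of the full read (default 0.4).
#' @return A one-row alignment data.frame, or `NULL` when unaligned.
#' @export
align_read <- function(bases, panel, read_id = "read", min_score_frac = 0.4) {
  best <- NULL
  for (ref_name in names(panel$amplicons)) {
    ref <- Biostrings::DNAString(panel$amplicons[[ref_name]])
    for (strand in c("+", "-")) {
      qry <- if (strand == "+") bases else revcomp(bases)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(qry), ref, type = "local",
        substitutionMatrix = sub_matrix(),
        gapOpening = aln_scores()$gap_open,
        gapExtension = aln_scores()$gap_extend)
      if (is.null(best) || Biostrings::score(aln) > best$score[1])
        best <- aln_to_row(aln, read_id, ref_name, strand, nchar(bases), qry)
    }
  }
  floor_score <- min_score_frac * nchar(bases) * aln_scores()$match
  if (best$score[1] < floor_score) return(NULL)
  best
}

#' Align a read set against the panel
#'
#' Batch version of [align_read()] with identical results on reads whose
#' reference/strand a k-mer vote identifies unambiguously (the overwhelming
#' majority); reads with no or ambiguous vote fall back to the exhaustive
#' per-read search. Reads below the score floor are dropped.
#'
#' @param reads A `read_set` data.frame.
#' @param panel A `reference_panel`.
#' @param min_score_frac Score floor fraction (see [align_read()]).
#' @return An alignment data.frame (class `alignment_set`), one row per
#'   aligned read.
#' @export
align_reads <- function(reads, panel, min_score_frac = 0.4) {
  empty <- structure(
    data.frame(read_id = character(0), ref = character(0),
               strand = character(0), score = numeric(0),
               identity = numeric(0), ref_start = integer(0),
               ref_end = integer(0), read_start = integer(0),
               read_end = integer(0), aligned = character(0),
               read_bases = character(0),
               read_len = integer(0), stringsAsFactors = FALSE),
    class = c("alignment_set", "data.frame"))
  if (nrow(reads) == 0L) return(empty)
  refs <- panel$amplicons
  k <- 14L
  env <- kmer_env(unname(refs), seq_along(refs), k)
  n <- nrow(reads)
  rc_bases <- revcomp(reads$bases)
  votes <- integer(n); vstrand <- character(n)
  for (i in seq_len(n)) {
    b <- reads$bases[i]
    stride <- max(10L, nchar(b) %/% 15L)
    hf <- kmer_lookup(env, b, k, stride)
    hr <- kmer_lookup(env, rc_bases[i], k, stride)
    if (length(hf) == 1L && !length(hr)) { votes[i] <- hf; vstrand[i] <- "+" }
    else if (length(hr) == 1L && !length(hf)) { votes[i] <- hr; vstrand[i] <- "-" }
    else { votes[i] <- NA_integer_; vstrand[i] <- NA_character_ }
  }
  groups <- list()
  for (r in seq_along(refs)) {
    for (strand in c("+", "-")) {
      idx <- which(!is.na(votes) & votes == r & vstrand == strand)
      if (!length(idx)) next
      qry <- if (strand == "+") reads$bases[idx] else rc_bases[idx]
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(qry),
        Biostrings::DNAString(refs[[r]]), type = "local",
        substitutionMatrix = sub_matrix(),
        gapOpening = aln_scores()$gap_open,
        gapExtension = aln_scores()$gap_extend)
      groups[[length(groups) + 1L]] <-
        aln_to_row(aln, reads$read_id[idx], names(refs)[r], strand,
                   nchar(reads$bases[idx]), qry)
    }
  }
  for (i in which(is.na(votes))) {
    row <- align_read(reads$bases[i], panel, read_id = reads$read_id[i],
                      min_score_frac = min_score_frac)
    if (!is.null(row)) groups[[length(groups) + 1L]] <- row
  }
  if (!length(groups)) return(empty)
  out <- do.call(rbind, groups)
  floor_score <- min_score_frac * out$read_len * aln_scores()$match
  out <- out[out$score >= floor_score, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alignment_set", "data.frame")
  out
}
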