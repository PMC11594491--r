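#' Parse an AS-PCR cell string
#'
#' Record tables encode the allele-specific PCR result for 1016 as a
#' space-separated list of band tokens: `V`/`G` for a strong band,
#' `weakV`/`weakG` for a weak one, `no call` for no band at all. Parsing is
#' loss-free: [format_aspcr()] reproduces the original string.
#'
#' @param text Cell string, e.g. `"weakV G"`.
#' @return An [aspcr_observation()].
#' @export
parse_aspcr <- function(text) {
  text <- trimws(text)
  if (text %in% c("no call", "not tested", ""))
    return(aspcr_observation("absent", "absent"))
  toks <- strsplit(text, "[[:space:]]+")[[1]]
  band_V <- "absent"; band_G <- "absent"
  for (tk in toks) {
    switch(tk,
           V = { band_V <- "strong" },
           weakV = { band_V <- "weak" },
           G = { band_G <- "strong" },
           weakG = { band_G <- "weak" },
           stop("unrecognized AS-PCR band token '", tk, "'"))
  }
  aspcr_observation(band_V, band_G)
}

#' @rdname parse_aspcr
#' @param obs An `aspcr_observation`.
#' @export
format_aspcr <- function(obs) {
  stopifnot(inherits(obs, "aspcr_observation"))
  if (obs$status == "no_call") return("no call")
  toks <- character(0)
  if (obs$band_V == "strong") toks <- c(toks, "V")
  if (obs$band_V == "weak") toks <- c(toks, "weakV")
  if (obs$band_G == "strong") toks <- c(toks, "G")
  if (obs$band_G == "weak") toks <- c(toks, "weakG")
  paste(toks, collapse = " ")
}

# Split a "ACCESSION-xx.xx%" COI cell into accession and numeric identity.
parse_coi <- function(text) {
  text <- trimws(text)
  if (text %in% c("no call", "not tested", ""))
    return(list(accession = NA_character_, pid = NA_real_, status = text))
  m <- regmatches(text, regexec("^(.*)-([0-9.]+)%$", text))[[1]]
  if (length(m) != 3L) stop("unparseable COI cell '", text, "'")
  list(accession = m[2], pid = as.numeric(m[3]), status = "called")
}

#' Read a multi-method genotyping record table
#'
#' The table layout mirrors the published comparison table: one row per
#' organism with columns `Sample`, `MCA 1016/1534`, `AS-PCR 1016`,
#' `Sanger 1016`, `NGS 989/1016/1534` and `COI Accession-%ID`, with the
#' literal strings `no call` and `not tested` where a method gave no result.
#'
#' @param path TSV path.
#' @return A data.frame of class `kdr_records` with columns `sample_id`
#'   (unique), `site` (the printed Sample label), `is_control`, `mca`,
#'   `aspcr`, `sanger`, `ngs`, `coi_accession`, `coi_pid`, `coi_status`.
#' @export
read_records_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("Sample", "MCA 1016/1534", "AS-PCR 1016", "Sanger 1016",
            "NGS 989/1016/1534", "COI Accession-%ID")
  if (!all(need %in% names(df)))
    stop("record TSV must have columns: ", paste(need, collapse = " | "))
  as_kdr_records(site = df[["Sample"]], mca = df[["MCA 1016/1534"]],
                 aspcr = df[["AS-PCR 1016"]], sanger = df[["Sanger 1016"]],
                 ngs = df[["NGS 989/1016/1534"]],
                 coi = df[["COI Accession-%ID"]])
}

#' Assemble a `kdr_records` table from raw column strings
#'
#' @param site Character vector of sample/site labels (control rows start
#'   with `"Control"`).
#' @param mca,aspcr,sanger,ngs,coi Character vectors of method cells (see
#'   [read_records_tsv()] for the encoding).
#' @param sample_id Optional unique sample identifiers; generated from the
#'   row number and site label when omitted.
#' @return A `kdr_records` data.frame.
#' @export
as_kdr_records <- function(site, mca, aspcr, sanger, ngs, coi,
                           sample_id = NULL) {
  n <- length(site)
  stopifnot(length(mca) == n, length(aspcr) == n, length(sanger) == n,
            length(ngs) == n, length(coi) == n)
  if (is.null(sample_id))
    sample_id <- sprintf("S%02d_%s", seq_len(n), gsub("[^A-Za-z0-9]", "", site))
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ","))
  coi_parsed <- lapply(coi, parse_coi)
  out <- data.frame(
    sample_id = sample_id, site = site,
    is_control = grepl("^Control", site),
    mca = trimws(mca), aspcr = trimws(aspcr), sanger = trimws(sanger),
    ngs = trimws(ngs),
    coi_accession = vapply(coi_parsed, `[[`, character(1), "accession"),
    coi_pid = vapply(coi_parsed, `[[`, numeric(1), "pid"),
    coi_status = vapply(coi_parsed, `[[`, character(1), "status"),
    stringsAsFactors = FALSE)
  # a row of all no-calls (the water blank) is still a legitimate record:
  # "no call" is an observation of absence, unlike "not tested"
  all_untested <- out$mca == "not tested" & out$aspcr == "not tested" &
    out$sanger == "not tested" & out$ngs == "not tested" &
    out$coi_status == "not tested"
  if (any(all_untested))
    stop("record(s) with no method observations: ",
         paste(out$sample_id[all_untested], collapse = ","))
  class(out) <- c("kdr_records", "data.frame")
  out
}

#' Write a `kdr_records` table in the published column layout
#'
#' @param records A `kdr_records` data.frame.
#' @param path Output TSV path.
#' @export
write_records_tsv <- function(records, path) {
  coi <- ifelse(records$coi_status %in% c("no call", "not tested"),
                records$coi_status,
                sprintf("%s-%s%%", records$coi_accession,
                        sub("\\.?0+$", "",
                            formatC(records$coi_pid, format = "f",
                                    digits = 2))))
  out <- data.frame(
    "Sample" = records$site, "MCA 1016/1534" = records$mca,
    "AS-PCR 1016" = records$aspcr, "Sanger 1016" = records$sanger,
    "NGS 989/1016/1534" = records$ngs, "COI Accession-%ID" = coi,
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Load the packaged 18-row multi-method comparison fixture
#'
#' A verbatim transcription of the published comparison of MCA, AS-PCR,
#' Sanger, amplicon-sequencing and COI results for 11 Osceola County field
#' samples and 7 control wells. The file checksum is verified so an
#' accidental edit of the transcription fails loudly.
#'
#' @return A `kdr_records` data.frame with 18 rows.
#' @export
#' @examples
#' tbl <- load_table1()
#' nrow(tbl)           # 18
#' sum(tbl$mca == "GIFC")
load_table1 <- function() {
  path <- system.file("extdata", "table1_multimethod.tsv", package = "kdrcall",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  expected <- "62e33c1440aaf6c780b05287be715cf4"
  if (!identical(md5, expected))
    stop("packaged record fixture failed its checksum (", md5,
         " != ", expected, "); the transcription has been altered")
  rec <- read_records_tsv(path)
  if (nrow(rec) != 18L) stop("fixture must have 18 rows")
  rec
}

# ---- per-record observation assembly ---------------------------------------

# 1016 observations carried by one record row (for the resolver).
record_observations <- function(row) {
  obs <- list()
  if (!row$mca %in% c("no call", "not tested")) {
    g <- parse_shorthand(row$mca)
    obs <- c(obs, list(genotype_observation(g[["1016"]], source = "MCA")))
  }
  if (!row$aspcr %in% c("no call", "not tested")) {
    obs <- c(obs, list(parse_aspcr(row$aspcr)))
  }
  if (!row$sanger %in% c("no call", "not tested")) {
    al <- strsplit(row$sanger, "")[[1]]
    obs <- c(obs, list(sanger_observation(al)))
  }
  if (!row$ngs %in% c("no call", "not tested")) {
    g <- parse_shorthand(row$ngs)
    obs <- c(obs, list(genotype_observation(g[["1016"]], source = "NGS")))
  }
  obs
}

mca_1016_has <- function(mca, allele) {
  vapply(mca, function(s) {
    if (s %in% c("no call", "not tested")) return(FALSE)
    allele %in% parse_shorthand(s)[["1016"]]
  }, logical(1), USE.NAMES = FALSE)
}

ngs_has <- function(ngs, locus, allele) {
  vapply(ngs, function(s) {
    if (s %in% c("no call", "not tested")) return(FALSE)
    allele %in% (parse_shorthand(s)[[locus]] %||% character(0))
  }, logical(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve every record's 1016 genotype across its methods
#'
#' Runs [resolve_1016()] on each row of a record table, trusting the
#' observations (a conflict between methods is reported as such, regardless
#' of any genotype implied by the sample label).
#'
#' @param records A `kdr_records` data.frame.
#' @param models Virtual assay model list.
#' @param strict_bands,min_methods Passed to [resolve_1016()].
#' @return `records` with added columns `resolved_1016` (genotype key,
#'   comma-joined if ambiguous, `""` if none), `resolution_status`, and
#'   `confirmed_alleles`.
#' @export
resolve_records <- function(records, models = virtual_assay_models(),
                            strict_bands = FALSE, min_methods = 2L) {
  stopifnot(inherits(records, "kdr_records"))
  res <- lapply(seq_len(nrow(records)), function(i) {
    resolve_1016(record_observations(records[i, , drop = FALSE]),
                 models = models, strict_bands = strict_bands,
                 min_methods = min_methods)
  })
  records$resolved_1016 <- vapply(res, function(r)
    paste(r$candidates, collapse = ","), character(1))
  records$resolution_status <- vapply(res, `[[`, character(1), "status")
  records$confirmed_alleles <- vapply(res, function(r) {
    if (is.null(r$confirmation)) return("")
    paste(r$confirmation$allele[r$confirmation$confirmed], collapse = ",")
  }, character(1))
  attr(records, "resolutions") <- res
  records
}

#' Multi-method concordance table and summary counts
#'
#' Tabulates a record table the way the published comparison table is read:
#' per-site and overall tallies of each MCA genotype string, per-method
#' counts of samples carrying at least one 1016G, the number of
#' sequencing-confirmed 1016G samples that also carry 989P, sequencing
#' no-calls, and COI identities at or above a threshold. Method-specific
#' G counts are reported both over field samples only (`field`) and over
#' all rows including controls (`all`); published per-method confirmation
#' sentences count field samples, while the sequencing no-call count
#' includes the water-blank control.
#'
#' @param records A `kdr_records` data.frame.
#' @param models Virtual assay model list (used for per-row resolution).
#' @param coi_threshold Percent-identity threshold (default 99).
#' @return An object of class `concordance_table`: list with `table` (the
#'   per-sample rows plus resolution columns) and `summary` (named list of
#'   counts).
#' @export
build_concordance <- function(records, models = virtual_assay_models(),
                              coi_threshold = 99) {
  stopifnot(inherits(records, "kdr_records"))
  if (anyDuplicated(records$sample_id))
    stop("duplicate sample_id in records")
  tab <- resolve_records(records, models = models)
  field <- !records$is_control

  g_by <- function(idx) {
    aspcr_g <- vapply(records$aspcr[idx], function(s)
      parse_aspcr(s)$band_G != "absent", logical(1), USE.NAMES = FALSE)
    sanger_g <- vapply(records$sanger[idx], function(s)
      !s %in% c("no call", "not tested") && grepl("G", s), logical(1),
      USE.NAMES = FALSE)
    c(MCA = sum(mca_1016_has(records$mca[idx], "G")),
      ASPCR = sum(aspcr_g),
      Sanger = sum(sanger_g),
      NGS = sum(ngs_has(records$ngs[idx], "1016", "G")))
  }

  ngs_g <- ngs_has(records$ngs, "1016", "G")
  ngs_p <- ngs_has(records$ngs, "989", "P")
  mca_called <- !records$mca %in% c("no call", "not tested")
  mca_tab_all <- table(records$mca[mca_called])
  mca_tab_site <- table(records$site[mca_called], records$mca[mca_called])

  summary <- list(
    n_records = nrow(records),
    n_field = sum(field),
    mca_counts = mca_tab_all,
    mca_counts_by_site = mca_tab_site,
    g_positive = list(field = g_by(field), all = g_by(rep(TRUE, nrow(records)))),
    ngs_p989_among_g = list(field = sum(ngs_g & ngs_p & field),
                            all = sum(ngs_g & ngs_p)),
    ngs_no_call = sum(records$ngs == "no call"),
    ngs_tested = sum(records$ngs != "not tested"),
    coi_tested = sum(records$coi_status == "called"),
    coi_pass = sum(records$coi_status == "called" &
                     records$coi_pid >= coi_threshold),
    coi_threshold = coi_threshold)
  structure(list(table = tab, summary = summary),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<concordance_table> %d records (%d field, %d control)\n",
              s$n_records, s$n_field, s$n_records - s$n_field))
  cat("MCA genotype tallies:\n"); print(s$mca_counts)
  cat(sprintf("1016G-positive (field): MCA %d, AS-PCR %d, Sanger %d, NGS %d\n",
              s$g_positive$field[["MCA"]], s$g_positive$field[["ASPCR"]],
              s$g_positive$field[["Sanger"]], s$g_positive$field[["NGS"]]))
  cat(sprintf("989P among NGS 1016G-positives (field): %d\n",
              s$ngs_p989_among_g$field))
  cat(sprintf("NGS no-calls among tested: %d of %d\n",
              s$ngs_no_call, s$ngs_tested))
  cat(sprintf("COI identity >= %g%%: %d of %d\n",
              s$coi_threshold, s$coi_pass, s$coi_tested))
  invisible(x)
}

#' JSON summary of a concordance table
#'
#' @param x A `concordance_table`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @export
concordance_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "concordance_table"))
  s <- x$summary
  obj <- list(
    n_records = s$n_records, n_field = s$n_field,
    mca_counts = as.list(s$mca_counts),
    g_positive_field = as.list(s$g_positive$field),
    g_positive_all = as.list(s$g_positive$all),
    ngs_p989_among_g_field = s$ngs_p989_among_g$field,
    ngs_no_call = s$ngs_no_call, ngs_tested = s$ngs_tested,
    coi_pass = s$coi_pass, coi_tested = s$coi_tested,
    coi_threshold = s$coi_threshold)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
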