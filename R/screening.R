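# Operational screening rules: control-panel completeness and the tiered /
# gatekeeper reflex-testing workflow for surveillance programs.

#' Define a screening control panel
#'
#' @param assays Named list: assay id -> character vector of alleles the
#'   assay must carry a control for. The default covers the full allele set
#'   of each assayed locus, because a non-target allele can produce signal
#'   (that is the failure mode the control set exists to catch).
#' @param controls Named list: control material name -> [multilocus_genotype()]
#'   (or `"negative"` for the blank).
#' @return A list of class `panel_definition`.
#' @export
panel_definition <- function(assays, controls) {
  structure(list(assays = assays, controls = controls),
            class = "panel_definition")
}

#' Default allele coverage required per assay
#'
#' All three 1016 alleles for either 1016 melt assay, both 1534 alleles for
#' the F1534C assay, both 989 alleles for the S989P assay.
#'
#' @return Named list assay id -> allele vector.
#' @export
default_assay_alleles <- function() {
  list(V1016I_MCA = c("V", "I", "G"), V1016G_MCA = c("V", "I", "G"),
       F1534C_MCA = c("F", "C"), S989P_MCA = c("S", "P"))
}

assay_locus_of <- function(assay_id) {
  switch(assay_id,
         V1016I_MCA = "1016", V1016G_MCA = "1016",
         F1534C_MCA = "1534", S989P_MCA = "989",
         stop("unknown assay id ", assay_id))
}

#' Validate a control panel
#'
#' A panel is valid when every allele of every assayed locus is carried
#' homozygously by at least one control material, at least one heterozygous
#' control carries each alternate allele of each assayed locus (so
#' competitive-primer balance is demonstrated), and a negative control is
#' present. Every missing (assay, allele) pair and heterozygous combination
#' is listed.
#'
#' @param panel A [panel_definition()].
#' @return List of class `panel_validity`: `valid` (logical),
#'   `missing_allele_controls` (data.frame assay/allele),
#'   `missing_het_controls` (data.frame assay/allele), `missing_negative`.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_definition"))
  ctrl <- panel$controls
  locus_pair <- function(g, locus) {
    if (identical(g, "negative")) return(NULL)
    g[[locus]]
  }
  miss_allele <- list(); miss_het <- list()
  for (aid in names(panel$assays)) {
    locus <- assay_locus_of(aid)
    for (a in panel$assays[[aid]]) {
      has_hom <- any(vapply(ctrl, function(g) {
        p <- locus_pair(g, locus)
        !is.null(p) && all(p == a)
      }, logical(1)))
      if (!has_hom)
        miss_allele[[length(miss_allele) + 1L]] <-
          data.frame(assay = aid, allele = a)
      ref <- kdr_loci()[[locus]]$reference_allele
      if (a != ref) {
        has_het <- any(vapply(ctrl, function(g) {
          p <- locus_pair(g, locus)
          !is.null(p) && a %in% p && p[1] != p[2]
        }, logical(1)))
        if (!has_het)
          miss_het[[length(miss_het) + 1L]] <-
            data.frame(assay = aid, allele = a)
      }
    }
  }
  missing_negative <- !any(vapply(ctrl, identical, logical(1), "negative"))
  bind <- function(x) if (length(x)) do.call(rbind, x)
    else data.frame(assay = character(0), allele = character(0))
  ma <- bind(miss_allele); mh <- bind(miss_het)
  structure(list(valid = nrow(ma) == 0L && nrow(mh) == 0L &&
                   !missing_negative,
                 missing_allele_controls = ma, missing_het_controls = mh,
                 missing_negative = missing_negative),
            class = "panel_validity")
}

#' @export
print.panel_validity <- function(x, ...) {
  cat("<panel_validity>", if (x$valid) "valid" else "INVALID", "\n")
  if (nrow(x$missing_allele_controls)) {
    cat("  missing allele controls:\n"); print(x$missing_allele_controls)
  }
  if (nrow(x$missing_het_controls)) {
    cat("  missing heterozygous controls:\n"); print(x$missing_het_controls)
  }
  if (x$missing_negative) cat("  missing negative control\n")
  invisible(x)
}

#' Screening strategies
#'
#' * `full_1016`: always run both 1016 melt assays (the only way to resolve
#'   all three alleles); [next_assays()] returns whichever has not yet run.
#' * `legacy_reflex`: keep the historical first tier (V1016I + F1534C) and
#'   reflex any sample showing at least one 1534F allele to the V1016G and
#'   S989P assays, exploiting the strong unidirectional linkage of 1016G
#'   with 1534F (1534C being fixed or nearly fixed where the legacy tier is
#'   used, the extra workload is small).
#'
#' @param name `"full_1016"` or `"legacy_reflex"`.
#' @param reflex_assays Reflex assay order (default V1016G then S989P).
#' @return A list of class `screening_strategy`.
#' @export
screening_strategy <- function(name = c("legacy_reflex", "full_1016"),
                               reflex_assays = c("V1016G_MCA", "S989P_MCA")) {
  name <- match.arg(name)
  if (name == "full_1016") {
    # both 1016 assays are first-tier; there is no reflex tier
    first_tier <- c("V1016I_MCA", "V1016G_MCA", "F1534C_MCA")
    reflex_assays <- character(0)
  } else {
    first_tier <- c("V1016I_MCA", "F1534C_MCA")
  }
  if (length(intersect(reflex_assays, first_tier)))
    stop("reflex assays must be disjoint from the first tier")
  structure(list(name = name, trigger_locus = "1534", trigger_allele = "F",
                 first_tier = first_tier, reflex_assays = reflex_assays),
            class = "screening_strategy")
}

#' Which assays to run next for a sample
#'
#' @param first_tier A partial [multilocus_genotype()] (or a 4-letter MCA
#'   shorthand string) carrying the first-tier results.
#' @param strategy A [screening_strategy()].
#' @param assays_run Character vector of assay ids already run (used by the
#'   `full_1016` strategy; defaults to the strategy's first tier).
#' @return Character vector of reflex assay ids (possibly empty), or an
#'   object of class `needs_more_data` when the trigger locus has no
#'   first-tier result yet.
#' @export
next_assays <- function(first_tier, strategy, assays_run = strategy$first_tier) {
  stopifnot(inherits(strategy, "screening_strategy"))
  if (is.character(first_tier)) first_tier <- parse_shorthand(first_tier)
  if (strategy$name == "full_1016")
    return(setdiff(c("V1016I_MCA", "V1016G_MCA"), assays_run))
  trig <- first_tier[[strategy$trigger_locus]]
  if (is.null(trig))
    return(structure(list(missing_locus = strategy$trigger_locus),
                     class = "needs_more_data"))
  if (strategy$trigger_allele %in% trig) strategy$reflex_assays
  else character(0)
}

#' Screen a cohort and tally the reflex workload
#'
#' For each record: the 1016 genotype resolved from the observations in
#' hand (via [resolve_1016()]), the reflex assays the strategy dispatches,
#' and the final resistance-ensemble class where resolvable.
#'
#' @param records A `kdr_records` data.frame (first-tier MCA results in the
#'   `mca` column) or a character vector of MCA shorthand strings.
#' @param strategy A [screening_strategy()].
#' @param models Virtual assay model list.
#' @return List of class `screening_plan`: `dispositions` (data.frame) and
#'   `summary` (n, reflex counts per assay).
#' @export
screen_cohort <- function(records, strategy = screening_strategy(),
                          models = virtual_assay_models()) {
  if (is.character(records)) {
    records <- as_kdr_records(site = rep("cohort", length(records)),
                              mca = records,
                              aspcr = rep("not tested", length(records)),
                              sanger = rep("not tested", length(records)),
                              ngs = rep("not tested", length(records)),
                              coi = rep("not tested", length(records)))
  }
  stopifnot(inherits(records, "kdr_records"))
  n <- nrow(records)
  reflex <- character(n); resolved <- character(n); ensemble <- character(n)
  n_reflex <- 0L
  for (i in seq_len(n)) {
    mca <- records$mca[i]
    if (mca %in% c("no call", "not tested")) {
      reflex[i] <- "needs_first_tier"; resolved[i] <- ""
      ensemble[i] <- NA_character_
      next
    }
    g <- parse_shorthand(mca)
    nx <- next_assays(g, strategy)
    if (inherits(nx, "needs_more_data")) {
      reflex[i] <- "needs_more_data"
    } else {
      reflex[i] <- paste(nx, collapse = ",")
      if (length(nx)) n_reflex <- n_reflex + 1L
    }
    res <- resolve_1016(record_observations(records[i, , drop = FALSE]),
                        models = models)
    resolved[i] <- paste(res$candidates, collapse = ",")
    ensemble[i] <- if (res$status == "resolved")
      classify_ensemble(multilocus_genotype(
        g1016 = strsplit(res$candidates, "")[[1]],
        g1534 = g[["1534"]])) else NA_character_
  }
  dispositions <- data.frame(sample_id = records$sample_id, mca = records$mca,
                             reflex_assays = reflex,
                             resolved_1016 = resolved,
                             ensemble = ensemble, stringsAsFactors = FALSE)
  structure(list(dispositions = dispositions,
                 summary = list(n = n, n_reflex_triggered = n_reflex,
                                strategy = strategy$name)),
            class = "screening_plan")
}

#' @export
print.screening_plan <- function(x, ...) {
  cat(sprintf("<screening_plan %s> %d samples, %d trigger reflex testing\n",
              x$summary$strategy, x$summary$n, x$summary$n_reflex_triggered))
  invisible(x)
}
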