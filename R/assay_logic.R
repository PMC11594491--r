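#' Virtual assay models for the 1016 locus
#'
#' The heart of the cross-assay resolution logic: for each assay, a total
#' map from the three 1016 alleles to the observable class that allele
#' produces in that assay. The maps encode the documented confusability of
#' the non-target allele:
#'
#' * `V1016I_MCA`: `V -> Vclass`, `G -> Vclass`, `I -> Iclass` — a 1016G
#'   allele melts like 1016V, so this assay alone cannot distinguish VV, VG
#'   and GG.
#' * `V1016G_MCA`: `G -> Gclass`, `V -> nonG`, `I -> nonG` — this assay
#'   establishes G vs not-G only, so VV, VI and II collide.
#' * `ASPCR_1016`: `V -> strongV`, `I -> weakV`, `G -> Gband` — a 1016I
#'   allele can amplify weakly with the 1016V-specific primer.
#'
#' @return Named list of `virtual_assay_model` objects, each with fields
#'   `assay_id` and `allele_to_class` (named character vector over V, I, G).
#' @export
virtual_assay_models <- function() {
  mk <- function(id, map) structure(list(assay_id = id, allele_to_class = map),
                                    class = "virtual_assay_model")
  list(
    V1016I_MCA = mk("V1016I_MCA", c(V = "Vclass", G = "Vclass", I = "Iclass")),
    V1016G_MCA = mk("V1016G_MCA", c(G = "Gclass", V = "nonG", I = "nonG")),
    ASPCR_1016 = mk("ASPCR_1016", c(V = "strongV", I = "weakV", G = "Gband"))
  )
}

#' @export
print.virtual_assay_model <- function(x, ...) {
  cat(sprintf("<virtual_assay_model %s> %s\n", x$assay_id,
              paste(names(x$allele_to_class), x$allele_to_class,
                    sep = "->", collapse = ", ")))
  invisible(x)
}

#' Predict what an assay reports for a true 1016 genotype
#'
#' The image of the allele pair under the assay's allele-to-class map: a
#' one-element set for a genotype whose two alleles produce the same
#' observable class (a homozygous pattern), two elements otherwise.
#'
#' @param alleles Length-2 character vector of 1016 alleles.
#' @param model A `virtual_assay_model`.
#' @return Sorted character vector of observable classes.
#' @export
#' @examples
#' m <- virtual_assay_models()
#' predict_assay_outcome(c("G", "G"), m$V1016I_MCA)  # "Vclass"
predict_assay_outcome <- function(alleles, model) {
  stopifnot(inherits(model, "virtual_assay_model"), length(alleles) == 2L)
  cls <- model$allele_to_class[alleles]
  if (anyNA(cls)) stop("allele(s) outside the model alphabet: ",
                       paste(alleles[is.na(cls)], collapse = ","))
  sort(unique(unname(cls)))
}

# ---- observation types ------------------------------------------------------

#' Observations consumed by the 1016 resolver
#'
#' Constructors for the per-method observation objects accepted by
#' [constraint_set()] and [resolve_1016()]:
#'
#' * `mca_observation()`: the observable-class set reported by one melt
#'   assay (from [call_mca()] or recorded directly).
#' * `aspcr_observation()`: the V- and G-band intensities of the
#'   allele-specific PCR (`"absent"`, `"weak"`, `"strong"`); no-call iff
#'   both bands absent.
#' * `sanger_observation()`: the 1016 alleles read from a chromatogram — a
#'   pair (exact genotype), a single symbol (allele present; a lone clean
#'   peak is not treated as proof of homozygosity because partner-allele
#'   dropout is observed in practice), or no-call.
#' * `genotype_observation()`: an exact 1016 diploid genotype asserted by a
#'   method that reads both alleles (the joint two-assay MCA string of a
#'   record table, or an amplicon-sequencing call), tagged with its source
#'   method.
#'
#' @param assay_id Assay identifier present in the model list.
#' @param classes Character vector of observed observable classes.
#' @param band_V,band_G `"absent"`, `"weak"` or `"strong"`.
#' @param alleles Character vector of 1016 allele symbols (length 1 or 2),
#'   or `NULL` for no-call.
#' @param source Method label used in confirmation bookkeeping.
#' @name observations
NULL

#' @rdname observations
#' @export
mca_observation <- function(assay_id, classes) {
  structure(list(assay_id = assay_id, classes = sort(unique(classes)),
                 status = if (length(classes)) "called" else "no_call"),
            class = c("mca_observation", "kdr_observation"))
}

#' @rdname observations
#' @export
aspcr_observation <- function(band_V = "absent", band_G = "absent") {
  lv <- c("absent", "weak", "strong")
  stopifnot(band_V %in% lv, band_G %in% lv)
  structure(list(band_V = band_V, band_G = band_G,
                 status = if (band_V == "absent" && band_G == "absent")
                   "no_call" else "called"),
            class = c("aspcr_observation", "kdr_observation"))
}

#' @rdname observations
#' @export
sanger_observation <- function(alleles = NULL) {
  if (!is.null(alleles)) stopifnot(all(alleles %in% c("V", "I", "G")),
                                   length(alleles) %in% 1:2)
  structure(list(alleles = alleles,
                 status = if (is.null(alleles)) "no_call" else "called"),
            class = c("sanger_observation", "kdr_observation"))
}

#' @rdname observations
#' @export
genotype_observation <- function(alleles, source = "NGS") {
  stopifnot(length(alleles) == 2L, all(alleles %in% c("V", "I", "G")))
  structure(list(alleles = alleles, source = source, status = "called"),
            class = c("genotype_observation", "kdr_observation"))
}

obs_source <- function(obs) {
  switch(class(obs)[1],
         mca_observation = obs$assay_id,
         aspcr_observation = "ASPCR",
         sanger_observation = "Sanger",
         genotype_observation = obs$source,
         stop("unknown observation type"))
}

all_1016_keys <- function() {
  vapply(enumerate_diploid_genotypes(kdr_loci()[["1016"]]),
         paste, character(1), collapse = "")
}

# ---- constraint sets --------------------------------------------------------

#' Genotypes at 1016 consistent with one observation
#'
#' Each called observation partitions the six diploid 1016 genotypes into
#' those consistent with it and those excluded. Melt-assay and exact
#' observations constrain by equality of the predicted class set; AS-PCR
#' bands constrain by presence semantics: a strong V band implies at least
#' one V allele, a weak V band at least one V or one I (the documented
#' cross-amplification), any G band at least one G. An absent band excludes
#' nothing under the default semantics, because band dropout is observed in
#' real records; `strict_bands = TRUE` makes an absent band exclude its
#' allele. A no-call observation returns the full genotype set.
#'
#' @param obs An observation (see [observations]).
#' @param models Virtual assay model list ([virtual_assay_models()]).
#' @param strict_bands Logical; strict AS-PCR absent-band semantics.
#' @return Character vector of genotype keys (subset of
#'   VV, VG, VI, GG, GI, II).
#' @export
constraint_set <- function(obs, models = virtual_assay_models(),
                           strict_bands = FALSE) {
  UseMethod("constraint_set")
}

#' @export
constraint_set.mca_observation <- function(obs, models = virtual_assay_models(),
                                           strict_bands = FALSE) {
  keys <- all_1016_keys()
  if (obs$status == "no_call") return(keys)
  model <- models[[obs$assay_id]]
  if (is.null(model)) stop("no virtual model for assay ", obs$assay_id)
  keep <- vapply(keys, function(k) {
    g <- strsplit(k, "")[[1]]
    setequal(predict_assay_outcome(g, model), obs$classes)
  }, logical(1))
  keys[keep]
}

#' @export
constraint_set.aspcr_observation <- function(obs,
                                             models = virtual_assay_models(),
                                             strict_bands = FALSE) {
  keys <- all_1016_keys()
  if (obs$status == "no_call") return(keys)
  keep <- vapply(keys, function(k) {
    g <- strsplit(k, "")[[1]]
    ok <- TRUE
    if (obs$band_V == "strong") ok <- ok && "V" %in% g
    if (obs$band_V == "weak")   ok <- ok && ("V" %in% g || "I" %in% g)
    if (obs$band_G %in% c("weak", "strong")) ok <- ok && "G" %in% g
    if (strict_bands) {
      if (obs$band_V == "absent") ok <- ok && !"V" %in% g
      if (obs$band_G == "absent") ok <- ok && !"G" %in% g
    }
    ok
  }, logical(1))
  keys[keep]
}

#' @export
constraint_set.sanger_observation <- function(obs,
                                              models = virtual_assay_models(),
                                              strict_bands = FALSE) {
  keys <- all_1016_keys()
  if (obs$status == "no_call") return(keys)
  if (length(obs$alleles) == 2L)
    return(keys[keys == genotype_key(kdr_loci()[["1016"]], obs$alleles)])
  keys[vapply(keys, function(k) obs$alleles %in% strsplit(k, "")[[1]],
              logical(1))]
}

#' @export
constraint_set.genotype_observation <- function(obs,
                                                models = virtual_assay_models(),
                                                strict_bands = FALSE) {
  keys <- all_1016_keys()
  keys[keys == genotype_key(kdr_loci()[["1016"]], obs$alleles)]
}

# Alleles unambiguously evidenced by one observation (its own class, band
# or base), used for the >= 2-method confirmation rule. Ambiguous signals
# (Vclass, nonG, weak V band) evidence nothing.
direct_detections <- function(obs, models = virtual_assay_models()) {
  switch(class(obs)[1],
    mca_observation = {
      model <- models[[obs$assay_id]]
      if (is.null(model) || obs$status == "no_call") return(character(0))
      # a class maps back to an allele unambiguously iff exactly one allele
      # produces it
      out <- character(0)
      for (cl in obs$classes) {
        src <- names(model$allele_to_class)[model$allele_to_class == cl]
        if (length(src) == 1L) out <- c(out, src)
      }
      out
    },
    aspcr_observation = {
      out <- character(0)
      if (obs$band_V == "strong") out <- c(out, "V")
      if (obs$band_G %in% c("weak", "strong")) out <- c(out, "G")
      out
    },
    sanger_observation = if (is.null(obs$alleles)) character(0)
                         else unique(obs$alleles),
    genotype_observation = unique(obs$alleles),
    character(0))
}

#' Resolve the 1016 genotype across methods
#'
#' Intersects the per-observation constraint sets over the six diploid 1016
#' genotypes. A singleton intersection is a resolved genotype; an empty one
#' is a conflict, reported with a minimal conflicting pair of methods when
#' one exists. Per-allele confirmation status is also computed: an allele
#' is `confirmed` when it is present in every candidate genotype and was
#' unambiguously detected (its own class, band or base) by at least
#' `min_methods` distinct methods.
#'
#' @param observations List of observation objects (see [observations]).
#' @param models Virtual assay model list.
#' @param strict_bands Passed to [constraint_set()].
#' @param min_methods Distinct-method threshold for confirmation (default 2).
#' @return An object of class `resolution_result` with fields `candidates`
#'   (character vector of genotype keys), `status`
#'   (`"resolved"`, `"ambiguous"`, `"conflict"`, `"no_call"`),
#'   `conflicting_methods`, `confirmation` (data.frame allele, detected_by,
#'   n_methods, confirmed).
#' @export
resolve_1016 <- function(observations, models = virtual_assay_models(),
                         strict_bands = FALSE, min_methods = 2L) {
  called <- Filter(function(o) o$status == "called", observations)
  keys <- all_1016_keys()
  if (!length(called))
    return(structure(list(candidates = character(0), status = "no_call",
                          conflicting_methods = NULL,
                          confirmation = NULL),
                     class = "resolution_result"))
  sets <- lapply(called, constraint_set, models = models,
                 strict_bands = strict_bands)
  cand <- Reduce(intersect, sets, keys)
  conflicting <- NULL
  status <- if (!length(cand)) "conflict"
            else if (length(cand) == 1L) "resolved" else "ambiguous"
  if (status == "conflict" && length(called) >= 2L) {
    for (i in seq_len(length(called) - 1L)) {
      for (j in (i + 1L):length(called)) {
        if (!length(intersect(sets[[i]], sets[[j]]))) {
          conflicting <- c(obs_source(called[[i]]), obs_source(called[[j]]))
          break
        }
      }
      if (!is.null(conflicting)) break
    }
    if (is.null(conflicting))
      conflicting <- vapply(called, obs_source, character(1))
  }

  det <- list(V = character(0), I = character(0), G = character(0))
  for (o in called) {
    src <- obs_source(o)
    for (a in direct_detections(o, models)) det[[a]] <- union(det[[a]], src)
  }
  in_all <- function(a) length(cand) > 0 &&
    all(vapply(cand, function(k) a %in% strsplit(k, "")[[1]], logical(1)))
  confirmation <- data.frame(
    allele = c("V", "I", "G"),
    detected_by = vapply(det, paste, character(1), collapse = ","),
    n_methods = vapply(det, length, integer(1)),
    in_all_candidates = vapply(c("V", "I", "G"), in_all, logical(1)),
    row.names = NULL)
  confirmation$confirmed <- confirmation$in_all_candidates &
    confirmation$n_methods >= min_methods
  structure(list(candidates = cand, status = status,
                 conflicting_methods = conflicting,
                 confirmation = confirmation),
            class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat("<resolution_result>", x$status)
  if (length(x$candidates))
    cat(": {", paste(x$candidates, collapse = ", "), "}", sep = "")
  if (!is.null(x$conflicting_methods))
    cat("  conflict between:", paste(x$conflicting_methods, collapse = " vs "))
  cat("\n")
  if (!is.null(x$confirmation)) {
    conf <- x$confirmation[x$confirmation$confirmed, , drop = FALSE]
    if (nrow(conf))
      cat("  confirmed alleles:",
          paste(sprintf("%s (%s)", conf$allele, conf$detected_by),
                collapse = "; "), "\n")
  }
  invisible(x)
}

#' Do a set of assays jointly disambiguate the 1016 genotypes?
#'
#' Computes the joint outcome signature of every diploid 1016 genotype
#' under all supplied models and checks injectivity. Running the V1016I and
#' V1016G melt assays together yields six distinct joint outcomes; either
#' assay alone collides on three genotypes.
#'
#' @param models List of `virtual_assay_model` objects.
#' @return A list with `injective` (logical) and `collisions` (list of
#'   genotype-key groups sharing a joint outcome; empty when injective).
#' @export
#' @examples
#' m <- virtual_assay_models()
#' disambiguation_check(m[c("V1016I_MCA", "V1016G_MCA")])$injective  # TRUE
disambiguation_check <- function(models) {
  stopifnot(length(models) >= 1L)
  keys <- all_1016_keys()
  sig <- vapply(keys, function(k) {
    g <- strsplit(k, "")[[1]]
    paste(vapply(models, function(m)
      paste(predict_assay_outcome(g, m), collapse = "+"), character(1)),
      collapse = " | ")
  }, character(1))
  groups <- split(keys, sig)
  collisions <- unname(groups[vapply(groups, length, integer(1)) > 1L])
  list(injective = length(collisions) == 0L, collisions = collisions)
}
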