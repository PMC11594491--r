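#' Construct a derivative melt curve
#'
#' A melt curve is the (baseline-subtracted, nonnegative) magnitude of the
#' fluorescence derivative over a strictly increasing temperature grid. The
#' instrument's sign convention (dF/dT vs -dF/dT) is irrelevant: any
#' nonnegative derivative magnitude is accepted.
#'
#' @param temperature Strictly increasing numeric grid, degrees C (at least
#'   50 points).
#' @param derivative Nonnegative derivative magnitudes, same length.
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, derivative) {
  stopifnot(is.numeric(temperature), is.numeric(derivative))
  if (length(temperature) != length(derivative))
    stop("temperature and derivative must have equal length")
  if (length(temperature) < 50L)
    stop("melt curve needs at least 50 grid points")
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing")
  if (any(derivative < 0))
    stop("derivative values must be nonnegative (baseline-subtracted magnitude)")
  structure(list(temperature = temperature, derivative = derivative),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> %d points, %.2f-%.2f degC, max derivative %.3g\n",
              length(x$temperature), min(x$temperature), max(x$temperature),
              max(x$derivative)))
  invisible(x)
}

#' @export
plot.melt_curve <- function(x, ...) {
  plot(x$temperature, x$derivative, type = "l",
       xlab = "temperature (°C)", ylab = "derivative (a.u.)", ...)
  pk <- find_peaks(x)
  if (nrow(pk)) graphics::abline(v = pk$tm, lty = 3)
  invisible(x)
}

#' Melt-curve assay definitions (control Tm fixture)
#'
#' Per-assay tables mapping Tm classes (the distinguishable product melting
#' temperatures observed in control wells) to their control Tm values, plus
#' the interpretation layer that folds Tm classes into the observable
#' classes the assay reports.
#'
#' The paper behind this package prints no absolute Tm values, only the
#' +/-0.3 degree calling window and the 0.8 degree offset of the 1016I
#' product below the 1016V product in the V1016G assay; control Tm values
#' are therefore run-supplied data from control wells, and the numbers here
#' are a synthetic fixture encoding the reported structure:
#'
#' * `V1016I_MCA`: V-class 79.0 (a 1016G allele also produces this product,
#'   which is the assay's documented blind spot), I-class 84.0.
#' * `V1016G_MCA`: G-class 80.0; non-G products at 84.0 (V) and 83.2 (I, the
#'   0.8 degree offset). Both non-G Tm classes fold into the single
#'   interpretive class `nonG`: the assay establishes G vs not-G only.
#' * `F1534C_MCA`: F-class 78.0, C-class 82.0.
#' * `S989P_MCA`: S-class 77.5, P-class 81.5 (reflex assay).
#'
#' `allele_tms` gives the product Tm generated by each allele (used by the
#' synthetic curve generator and to derive expected control classes);
#' `class_map` maps Tm class to interpretive observable class.
#'
#' @param tolerance Calling window half-width in degrees C (default 0.3).
#' @param min_rel_height Fraction of the tallest peak a secondary peak must
#'   reach to be counted (default 0.2).
#' @return Named list of `assay_definition` objects.
#' @export
default_assay_definitions <- function(tolerance = 0.3, min_rel_height = 0.2) {
  list(
    V1016I_MCA = assay_definition(
      assay_id = "V1016I_MCA", locus = "1016",
      class_tms = c(Vclass = 79.0, Iclass = 84.0),
      class_map = c(Vclass = "Vclass", Iclass = "Iclass"),
      allele_tm_class = c(V = "Vclass", G = "Vclass", I = "Iclass"),
      tolerance = tolerance, min_rel_height = min_rel_height),
    V1016G_MCA = assay_definition(
      assay_id = "V1016G_MCA", locus = "1016",
      class_tms = c(Gclass = 80.0, Inear = 83.2, nonG = 84.0),
      class_map = c(Gclass = "Gclass", Inear = "nonG", nonG = "nonG"),
      allele_tm_class = c(G = "Gclass", I = "Inear", V = "nonG"),
      tolerance = tolerance, min_rel_height = min_rel_height,
      confusable = list(c("Inear", "nonG"))),
    F1534C_MCA = assay_definition(
      assay_id = "F1534C_MCA", locus = "1534",
      class_tms = c(Fclass = 78.0, Cclass = 82.0),
      class_map = c(Fclass = "Fclass", Cclass = "Cclass"),
      allele_tm_class = c(F = "Fclass", C = "Cclass"),
      tolerance = tolerance, min_rel_height = min_rel_height),
    S989P_MCA = assay_definition(
      assay_id = "S989P_MCA", locus = "989",
      class_tms = c(Sclass = 77.5, Pclass = 81.5),
      class_map = c(Sclass = "Sclass", Pclass = "Pclass"),
      allele_tm_class = c(S = "Sclass", P = "Pclass"),
      tolerance = tolerance, min_rel_height = min_rel_height)
  )
}

#' Define a melt-curve assay
#'
#' @param assay_id Assay identifier.
#' @param locus Name of the locus the assay interrogates.
#' @param class_tms Named numeric vector: Tm class -> control Tm (degrees C).
#' @param class_map Named character vector: Tm class -> interpretive
#'   observable class. Defaults to identity.
#' @param allele_tm_class Named character vector: allele -> Tm class of the
#'   product that allele generates.
#' @param tolerance Calling window half-width, degrees C (> 0).
#' @param min_rel_height Secondary-peak relative height threshold.
#' @param confusable List of Tm-class pairs documented as closer than
#'   2*tolerance (exempt from the spacing check).
#' @return An `assay_definition` object.
#' @export
assay_definition <- function(assay_id, locus, class_tms,
                             class_map = stats::setNames(names(class_tms),
                                                         names(class_tms)),
                             allele_tm_class, tolerance = 0.3,
                             min_rel_height = 0.2, confusable = list()) {
  stopifnot(tolerance > 0, is.numeric(class_tms), !is.null(names(class_tms)),
            all(names(class_map) %in% names(class_tms)),
            all(allele_tm_class %in% names(class_tms)))
  cls <- names(class_tms)
  if (length(cls) >= 2) {
    for (i in seq_len(length(cls) - 1L)) for (j in (i + 1L):length(cls)) {
      d <- abs(class_tms[i] - class_tms[j])
      pair_ok <- any(vapply(confusable, function(p)
        setequal(p, cls[c(i, j)]), logical(1)))
      if (d <= 2 * tolerance && !pair_ok)
        stop("Tm classes ", cls[i], " and ", cls[j], " in assay ", assay_id,
             " are closer than 2*tolerance and not documented as confusable")
    }
  }
  structure(list(assay_id = assay_id, locus = locus, class_tms = class_tms,
                 class_map = class_map, allele_tm_class = allele_tm_class,
                 tolerance = tolerance, min_rel_height = min_rel_height,
                 confusable = confusable),
            class = "assay_definition")
}

#' @export
print.assay_definition <- function(x, ...) {
  cat(sprintf("<assay_definition %s> locus %s, tolerance ±%.2f °C\n",
              x$assay_id, x$locus, x$tolerance))
  print(x$class_tms)
  invisible(x)
}

# Interpretive classes expected for a diploid genotype under this assay.
expected_classes <- function(assay, alleles) {
  tmc <- assay$allele_tm_class[alleles]
  if (anyNA(tmc)) stop("allele(s) ", paste(alleles[is.na(tmc)], collapse = ","),
                       " unknown to assay ", assay$assay_id)
  sort(unique(unname(assay$class_map[tmc])))
}

#' Detect derivative melt-curve peaks
#'
#' Local maxima of the lightly smoothed derivative (centered moving average,
#' default window 5 grid points). Peak Tm is refined by parabolic
#' interpolation through the three grid points around each maximum. Peaks
#' below `min_rel_height` of the tallest peak, or below the absolute
#' `noise_floor`, are discarded; at most the 3 tallest are returned (height
#' descending).
#'
#' @param curve A [melt_curve()].
#' @param min_rel_height Relative height threshold (fraction of global max).
#' @param smooth_window Moving-average window in grid points (odd).
#' @param noise_floor Absolute derivative magnitude below which a curve is
#'   considered flat.
#' @return A data.frame with columns `tm`, `height`, `prominence`, sorted by
#'   height descending (0 rows for a flat curve).
#' @export
find_peaks <- function(curve, min_rel_height = 0.2, smooth_window = 5L,
                       noise_floor = 0.05) {
  stopifnot(inherits(curve, "melt_curve"), smooth_window %% 2L == 1L)
  tt <- curve$temperature
  y <- as.numeric(stats::filter(curve$derivative,
                                rep(1 / smooth_window, smooth_window),
                                sides = 2))
  # moving average is NA at the edges; edges cannot host a refined peak anyway
  y[is.na(y)] <- 0
  n <- length(y)
  gmax <- max(y)
  empty <- data.frame(tm = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  if (gmax <= noise_floor) return(empty)
  i <- 2:(n - 1L)
  is_max <- y[i] > y[i - 1L] & y[i] >= y[i + 1L]
  cand <- i[is_max]
  if (!length(cand)) return(empty)
  # drop plateau duplicates: keep first index of runs of equal height
  keep <- c(TRUE, diff(cand) > 1L | y[cand[-1L]] != y[cand[-length(cand)]])
  cand <- cand[keep]
  height <- y[cand]
  sel <- height >= min_rel_height * gmax & height > noise_floor
  cand <- cand[sel]; height <- height[sel]
  if (!length(cand)) return(empty)
  # parabolic refinement of the apex position
  tm <- vapply(cand, function(k) {
    y0 <- y[k - 1L]; y1 <- y[k]; y2 <- y[k + 1L]
    denom <- y0 - 2 * y1 + y2
    if (denom >= 0) return(tt[k])
    delta <- 0.5 * (y0 - y2) / denom
    delta <- max(-0.5, min(0.5, delta))
    tt[k] + delta * (tt[k + 1L] - tt[k])
  }, numeric(1))
  # prominence: drop from peak to the highest saddle separating it from any
  # taller peak (global max gets its own height)
  prominence <- vapply(seq_along(cand), function(p) {
    k <- cand[p]; h <- height[p]
    taller <- cand[height > h]
    if (!length(taller)) return(h)
    saddle <- -Inf
    for (tk in taller) {
      rng <- if (tk < k) tk:k else k:tk
      saddle <- max(saddle, min(y[rng]))
    }
    h - saddle
  }, numeric(1))
  out <- data.frame(tm = tm, height = height, prominence = prominence)
  out <- out[order(-out$height), , drop = FALSE]
  if (nrow(out) > 3L) out <- out[1:3, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call a melt-curve assay from detected peaks
#'
#' Each peak is assigned to the Tm class whose control Tm lies within
#' `assay$tolerance` of the peak Tm; if two classes qualify the nearest wins
#' and a warning flag is attached. Unassignable peaks are ignored (with a
#' warning flag). Assigned Tm classes are folded to interpretive observable
#' classes through the assay's `class_map`: one class is a
#' homozygous-pattern call, two a heterozygous-pattern call, zero a no-call.
#'
#' @param peaks Data.frame from [find_peaks()] (columns `tm`, `height`).
#' @param assay An [assay_definition()].
#' @return An object of class `mca_call` with fields `assay_id`,
#'   `detected_classes` (interpretive), `tm_classes`, `status`
#'   (`"called"`/`"no_call"`), `no_call_reason`, `warnings`, `assignments`.
#' @export
call_mca <- function(peaks, assay) {
  stopifnot(inherits(assay, "assay_definition"))
  mk <- function(classes, tm_classes, status, reason, warnings, assignments) {
    structure(list(assay_id = assay$assay_id, detected_classes = classes,
                   tm_classes = tm_classes, status = status,
                   no_call_reason = reason, warnings = warnings,
                   assignments = assignments),
              class = "mca_call")
  }
  if (is.null(peaks) || nrow(peaks) == 0L)
    return(mk(character(0), character(0), "no_call", "no amplification",
              character(0), NULL))
  warnings <- character(0)
  cls <- names(assay$class_tms)
  assigned <- character(nrow(peaks))
  for (p in seq_len(nrow(peaks))) {
    d <- abs(assay$class_tms - peaks$tm[p])
    within <- which(d <= assay$tolerance + 1e-9)
    if (!length(within)) {
      assigned[p] <- NA_character_
      warnings <- c(warnings, sprintf(
        "peak at %.2f °C not within ±%.2f °C of any control; ignored",
        peaks$tm[p], assay$tolerance))
    } else {
      if (length(within) > 1L)
        warnings <- c(warnings, sprintf(
          "peak at %.2f °C within tolerance of classes %s; nearest used",
          peaks$tm[p], paste(cls[within], collapse = ",")))
      assigned[p] <- cls[within[which.min(d[within])]]
    }
  }
  assignments <- data.frame(tm = peaks$tm, height = peaks$height,
                            tm_class = assigned)
  tm_classes <- sort(unique(assigned[!is.na(assigned)]))
  if (!length(tm_classes))
    return(mk(character(0), character(0), "no_call",
              "no peak within tolerance", warnings, assignments))
  detected <- sort(unique(unname(assay$class_map[tm_classes])))
  mk(detected, tm_classes, "called", NA_character_, warnings, assignments)
}

#' @export
print.mca_call <- function(x, ...) {
  if (x$status == "called") {
    pat <- if (length(x$detected_classes) == 1L) "homozygous-pattern"
           else "heterozygous-pattern"
    cat(sprintf("<mca_call %s> %s: {%s}\n", x$assay_id, pat,
                paste(x$detected_classes, collapse = ", ")))
  } else {
    cat(sprintf("<mca_call %s> no_call (%s)\n", x$assay_id, x$no_call_reason))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Validate an MCA run from its control wells
#'
#' A run is valid when every homozygous allele control yields exactly its
#' own class, every heterozygous control yields both expected classes, and
#' the negative control yields a no-call. A failed heterozygous control
#' downgrades the run to `"valid_with_warning"` rather than invalid (a
#' competitive-primer imbalance is worth flagging, but homozygote calls on
#' unknowns remain interpretable); a failed homozygous or negative control,
#' or a missing required control, invalidates the run.
#'
#' @param control_calls Named list of [call_mca()] results, one per control
#'   well.
#' @param control_genotypes Named list giving each control's labeled content:
#'   a length-2 allele vector at the assay locus, or the string
#'   `"negative"`.
#' @param assay The [assay_definition()] being validated.
#' @param required_hets List of allele pairs that must appear among the
#'   heterozygous controls. Default: each alternate allele of the assay
#'   locus paired in at least one het control.
#' @return A list of class `run_validity` with fields `status`
#'   (`"valid"`, `"valid_with_warning"`, `"invalid"`), `failures`
#'   (data.frame control/expected/observed/severity), `missing`.
#' @export
validate_controls <- function(control_calls, control_genotypes, assay,
                              required_hets = NULL) {
  stopifnot(inherits(assay, "assay_definition"))
  loci <- kdr_loci()
  locus <- loci[[assay$locus]]
  alleles <- names(assay$allele_tm_class)

  missing <- character(0)
  # required: a homozygous control for every allele, het coverage, a negative
  hom_of <- function(a) vapply(control_genotypes, function(g)
    is.character(g) && length(g) == 2L && all(g == a), logical(1))
  for (a in alleles)
    if (!any(hom_of(a))) missing <- c(missing, paste0("homozygous ", a))
  het_names <- names(control_genotypes)[vapply(control_genotypes, function(g)
    is.character(g) && length(g) == 2L && g[1] != g[2], logical(1))]
  if (is.null(required_hets))
    required_hets <- lapply(locus$alternate_alleles, function(a) a)
  for (rh in required_hets) {
    covered <- any(vapply(het_names, function(nm)
      all(rh %in% control_genotypes[[nm]]), logical(1)))
    if (!covered)
      missing <- c(missing, paste0("heterozygous control carrying ",
                                   paste(rh, collapse = "/")))
  }
  if (!any(vapply(control_genotypes, function(g)
    identical(g, "negative"), logical(1))))
    missing <- c(missing, "negative")
  if (length(missing))
    return(structure(list(status = "invalid",
                          failures = data.frame(), missing = missing,
                          reason = "control absent"),
                     class = "run_validity"))

  failures <- data.frame(control = character(0), expected = character(0),
                         observed = character(0), severity = character(0))
  for (nm in names(control_genotypes)) {
    g <- control_genotypes[[nm]]
    call <- control_calls[[nm]]
    if (is.null(call)) {
      failures <- rbind(failures, data.frame(
        control = nm, expected = "call present", observed = "no call object",
        severity = "invalid"))
      next
    }
    if (identical(g, "negative")) {
      if (call$status != "no_call")
        failures <- rbind(failures, data.frame(
          control = nm, expected = "no_call",
          observed = paste(call$detected_classes, collapse = ","),
          severity = "invalid"))
      next
    }
    exp_cls <- expected_classes(assay, g)
    obs <- if (call$status == "called") call$detected_classes else character(0)
    ok <- setequal(obs, exp_cls)
    if (!ok) {
      severity <- if (g[1] != g[2]) "warning" else "invalid"
      failures <- rbind(failures, data.frame(
        control = nm, expected = paste(exp_cls, collapse = ","),
        observed = if (length(obs)) paste(obs, collapse = ",") else
          paste0("no_call (", call$no_call_reason, ")"),
        severity = severity))
    }
  }
  status <- if (any(failures$severity == "invalid")) "invalid"
            else if (any(failures$severity == "warning")) "valid_with_warning"
            else "valid"
  structure(list(status = status, failures = failures,
                 missing = character(0), reason = NA_character_),
            class = "run_validity")
}

#' @export
print.run_validity <- function(x, ...) {
  cat("<run_validity>", x$status, "\n")
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = "; "), "\n")
  if (nrow(x$failures)) print(x$failures)
  invisible(x)
}

#' Read melt curves from long-format CSV
#'
#' Expected columns: `sample_id`, `assay_id`, `temperature_C`, `derivative`.
#'
#' @param path CSV file path.
#' @return Named nested list: `curves[[sample_id]][[assay_id]]` is a
#'   [melt_curve()].
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay_id", "temperature_C", "derivative")
  if (!all(need %in% names(df)))
    stop("curves CSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (sid in unique(df$sample_id)) {
    di <- df[df$sample_id == sid, ]
    out[[sid]] <- list()
    for (aid in unique(di$assay_id)) {
      dj <- di[di$assay_id == aid, ]
      dj <- dj[order(dj$temperature_C), ]
      out[[sid]][[aid]] <- melt_curve(dj$temperature_C, dj$derivative)
    }
  }
  out
}

#' Write melt curves to long-format CSV
#'
#' @param curves Nested list as returned by [read_curves_csv()].
#' @param path Output CSV path.
#' @export
write_curves_csv <- function(curves, path) {
  rows <- list()
  for (sid in names(curves)) for (aid in names(curves[[sid]])) {
    cv <- curves[[sid]][[aid]]
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid, assay_id = aid,
      temperature_C = cv$temperature, derivative = cv$derivative)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}
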