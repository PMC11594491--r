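#' Packaged kdr loci
#'
#' The three voltage-gated sodium-channel (NaV) positions screened for
#' knockdown resistance in *Aedes aegypti*, numbered by the standard
#' *Musca domestica* convention: 989 (S reference; P resistant),
#' 1016 (V reference; I and G resistant) and 1534 (F reference; C resistant).
#'
#' `canonical_order` fixes the per-locus allele print order used by the
#' shorthand notation (989: S before P; 1016: V, G, I; 1534: F before C), so
#' that e.g. a 1016 V/G heterozygote always prints "VG" and a G/I
#' heterozygote "GI". The order is data on the locus object, not a global
#' rule, and can be overridden via [kdr_locus()] for user-supplied loci.
#'
#' @return A named list of `kdr_locus` objects with elements `"989"`,
#'   `"1016"` and `"1534"`.
#' @seealso [kdr_locus()], [parse_shorthand()], [format_shorthand()]
#' @export
#' @examples
#' kdr_loci()[["1016"]]
kdr_loci <- function() {
  list(
    "989"  = kdr_locus("989",  reference = "S", alternates = "P",
                       canonical_order = c("S", "P")),
    "1016" = kdr_locus("1016", reference = "V", alternates = c("I", "G"),
                       canonical_order = c("V", "G", "I")),
    "1534" = kdr_locus("1534", reference = "F", alternates = "C",
                       canonical_order = c("F", "C"))
  )
}

#' Define a kdr locus
#'
#' @param name Locus identifier (residue number as character, e.g. `"1016"`).
#' @param reference Reference amino-acid symbol.
#' @param alternates Character vector of alternate amino-acid symbols.
#' @param canonical_order Permutation of `c(reference, alternates)` giving the
#'   allele print order for shorthand genotype strings. Defaults to
#'   reference first, then alternates as given.
#' @param residue_number Integer residue number (*M. domestica* numbering);
#'   defaults to `as.integer(name)`.
#' @return An object of class `kdr_locus`.
#' @export
kdr_locus <- function(name, reference, alternates,
                      canonical_order = c(reference, alternates),
                      residue_number = as.integer(name)) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(reference), length(reference) == 1L,
            is.character(alternates), length(alternates) >= 0L)
  if (reference %in% alternates)
    stop("reference allele must not appear among alternates for locus ", name)
  alleles <- c(reference, alternates)
  if (!setequal(canonical_order, alleles) ||
      length(canonical_order) != length(alleles))
    stop("canonical_order must be a permutation of the allele set for locus ",
         name)
  structure(
    list(name = name, residue_number = residue_number,
         reference_allele = reference, alternate_alleles = alternates,
         alleles = alleles, canonical_order = canonical_order),
    class = "kdr_locus"
  )
}

#' @export
print.kdr_locus <- function(x, ...) {
  cat(sprintf("<kdr_locus %s> alleles: %s (reference %s)\n",
              x$name, paste(x$canonical_order, collapse = "/"),
              x$reference_allele))
  invisible(x)
}

# Sort an allele pair into the locus's canonical print order.
canonical_pair <- function(locus, alleles) {
  stopifnot(length(alleles) == 2L)
  bad <- setdiff(alleles, locus$alleles)
  if (length(bad))
    stop("allele(s) ", paste(bad, collapse = ","),
         " not in the allele set of locus ", locus$name)
  unname(alleles[order(match(alleles, locus$canonical_order))])
}

# Key for an unordered diploid genotype, e.g. "VG" (canonical order).
genotype_key <- function(locus, alleles) {
  paste(canonical_pair(locus, alleles), collapse = "")
}

#' Enumerate all unordered diploid genotypes at a locus
#'
#' For a locus with k alleles there are k(k+1)/2 unordered pairs. The order
#' is deterministic: pairs are generated by walking the canonical allele
#' order, so locus 1016 yields VV, VG, VI, GG, GI, II.
#'
#' @param locus A `kdr_locus`.
#' @return A list of length-2 character vectors, each in canonical order.
#' @export
#' @examples
#' sapply(enumerate_diploid_genotypes(kdr_loci()[["1016"]]), paste, collapse = "")
enumerate_diploid_genotypes <- function(locus) {
  ord <- locus$canonical_order
  k <- length(ord)
  out <- vector("list", k * (k + 1L) / 2L)
  idx <- 1L
  for (i in seq_len(k)) {
    for (j in i:k) {
      out[[idx]] <- c(ord[i], ord[j])
      idx <- idx + 1L
    }
  }
  out
}

#' Construct a multi-locus kdr genotype
#'
#' An unordered diploid allele pair at each of the loci 989 (optional), 1016
#' and 1534. This is the object the shorthand strings ("SSGIFC", "VGFC")
#' serialize.
#'
#' @param g1016,g1534 Length-2 character vectors of alleles (any order).
#' @param g989 Length-2 character vector, or `NULL` when 989 was not assayed.
#'   A 4-letter shorthand leaves 989 unknown; it is never assumed "SS".
#' @param loci Locus set, defaulting to [kdr_loci()].
#' @return An object of class `multilocus_genotype`: a named list with
#'   elements `"989"` (possibly `NULL`), `"1016"`, `"1534"`, each a canonical
#'   allele pair.
#' @export
#' @examples
#' multilocus_genotype(g1016 = c("I", "G"), g1534 = c("C", "F"))
multilocus_genotype <- function(g1016, g1534, g989 = NULL, loci = kdr_loci()) {
  out <- list(
    "989"  = if (!is.null(g989)) canonical_pair(loci[["989"]], g989),
    "1016" = canonical_pair(loci[["1016"]], g1016),
    "1534" = canonical_pair(loci[["1534"]], g1534)
  )
  structure(out, class = "multilocus_genotype")
}

#' @export
print.multilocus_genotype <- function(x, ...) {
  cat("<multilocus_genotype>", format_shorthand(x))
  if (is.null(x[["989"]])) cat("  (989 unknown)")
  cat("\n")
  invisible(x)
}

#' @export
format.multilocus_genotype <- function(x, ...) format_shorthand(x)

# Order-insensitive equality of multilocus genotypes (pairs are canonical).
#' @export
`==.multilocus_genotype` <- function(e1, e2) {
  identical(unclass(e1), unclass(e2))
}

#' Parse a shorthand kdr genotype string
#'
#' A 6-letter string covers 989/1016/1534 ("SSGIFC"); a 4-letter string
#' covers 1016/1534 only ("GIFC") and leaves 989 unknown. Letters are read
#' positionally, two per locus, and must belong to the locus alphabet at
#' that position.
#'
#' @param text 4- or 6-character genotype string.
#' @param loci Locus set, defaulting to [kdr_loci()].
#' @return A [multilocus_genotype()].
#' @export
#' @examples
#' parse_shorthand("SSGIFC")
#' parse_shorthand("VVFF")
parse_shorthand <- function(text, loci = kdr_loci()) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- nchar(text)
  if (!n %in% c(4L, 6L))
    stop("invalid shorthand '", text, "': length must be 4 (1016+1534) or 6 ",
         "(989+1016+1534), got ", n)
  chars <- strsplit(text, "")[[1]]
  locus_seq <- if (n == 6L) c("989", "1016", "1534") else c("1016", "1534")
  pairs <- list()
  for (k in seq_along(locus_seq)) {
    lname <- locus_seq[k]
    locus <- loci[[lname]]
    pos <- (2L * k - 1L):(2L * k)
    a <- chars[pos]
    bad <- which(!a %in% locus$alleles)
    if (length(bad))
      stop("invalid shorthand '", text, "': letter '", a[bad[1]],
           "' at position ", pos[bad[1]], " is not an allele of locus ",
           lname)
    pairs[[lname]] <- a
  }
  multilocus_genotype(g1016 = pairs[["1016"]], g1534 = pairs[["1534"]],
                      g989 = pairs[["989"]], loci = loci)
}

#' Format a multi-locus genotype as a shorthand string
#'
#' Inverse of [parse_shorthand()]: each locus's pair is printed in the
#' locus's canonical order; 989 is included only when present.
#'
#' @param g A `multilocus_genotype`.
#' @param loci Locus set, defaulting to [kdr_loci()].
#' @return A 4- or 6-character string.
#' @export
#' @examples
#' format_shorthand(multilocus_genotype(c("G", "V"), c("C", "F")))  # "VGFC"
format_shorthand <- function(g, loci = kdr_loci()) {
  stopifnot(inherits(g, "multilocus_genotype"))
  if (is.null(g[["1016"]]) || is.null(g[["1534"]]))
    stop("incomplete genotype: calls at 1016 and 1534 are required for shorthand")
  parts <- character(0)
  for (lname in c("989", "1016", "1534")) {
    if (is.null(g[[lname]])) next
    parts <- c(parts, paste(canonical_pair(loci[[lname]], g[[lname]]),
                            collapse = ""))
  }
  paste(parts, collapse = "")
}

#' Classify a genotype into a kdr ensemble
#'
#' The two resistance ensembles with known strong pyrethroid-resistance
#' phenotypes are geographically structured: 1016I with 1534C in the Western
#' Hemisphere, and 989P with 1016G in the Indopacific. Classification rule:
#'
#' * `western_hemisphere`: at least one 1016I and one 1534C, and no G or P;
#' * `indopacific`: at least one 1016G and/or 989P, and no 1016I;
#' * `mixed`: an Indopacific allele (G or P) together with 1016I;
#' * `susceptible_like`: VV at 1016, FF at 1534, and SS or unknown at 989;
#' * `other`: anything else (e.g. IIFF, VVCC).
#'
#' The labels are mutually exclusive and the rule is total over genotypes
#' with 1016 and 1534 called.
#'
#' @param g A `multilocus_genotype` (or shorthand string, parsed first).
#' @return One of `"western_hemisphere"`, `"indopacific"`, `"mixed"`,
#'   `"susceptible_like"`, `"other"`.
#' @export
#' @examples
#' classify_ensemble("SSIICC")   # western_hemisphere
#' classify_ensemble("PPGGFF")   # indopacific
#' classify_ensemble("SPGIFC")   # mixed
classify_ensemble <- function(g) {
  if (is.character(g)) g <- parse_shorthand(g)
  stopifnot(inherits(g, "multilocus_genotype"))
  a1016 <- g[["1016"]]; a1534 <- g[["1534"]]; a989 <- g[["989"]]
  has_I <- "I" %in% a1016
  has_G <- "G" %in% a1016
  has_P <- !is.null(a989) && "P" %in% a989
  has_C <- "C" %in% a1534
  indo_allele <- has_G || has_P
  if (indo_allele && has_I) return("mixed")
  if (indo_allele) return("indopacific")
  if (has_I && has_C) return("western_hemisphere")
  if (identical(a1016, c("V", "V")) && identical(a1534, c("F", "F")) &&
      (is.null(a989) || identical(a989, c("S", "S"))))
    return("susceptible_like")
  "other"
}

#' All 54 full multi-locus genotypes over the packaged loci
#'
#' Cartesian product of the 3 diploid genotypes at 989, 6 at 1016 and 3 at
#' 1534, in deterministic (989-major) order.
#'
#' @return A list of 54 `multilocus_genotype` objects.
#' @export
all_multilocus_genotypes <- function() {
  loci <- kdr_loci()
  g989 <- enumerate_diploid_genotypes(loci[["989"]])
  g1016 <- enumerate_diploid_genotypes(loci[["1016"]])
  g1534 <- enumerate_diploid_genotypes(loci[["1534"]])
  out <- list()
  for (a in g989) for (b in g1016) for (d in g1534)
    out[[length(out) + 1L]] <- multilocus_genotype(b, d, g989 = a, loci = loci)
  out
}

#' JSON serialization of a multi-locus genotype
#'
#' Explicit locus keys; an unknown 989 is serialized as `null`.
#'
#' @param g A `multilocus_genotype`.
#' @return A JSON string.
#' @export
genotype_to_json <- function(g) {
  stopifnot(inherits(g, "multilocus_genotype"))
  jsonlite::toJSON(unclass(g), auto_unbox = FALSE, null = "null")
}

#' @rdname genotype_to_json
#' @param json JSON string produced by [genotype_to_json()].
#' @export
genotype_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  multilocus_genotype(g1016 = x[["1016"]], g1534 = x[["1534"]],
                      g989 = x[["989"]])
}
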