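# Seeded generators emulating the study's data-generating processes:
# Gaussian-peak derivative melt curves per observable allele class, diploid
# cohorts with the documented kdr haplotype linkage, barcoded diploid
# amplicon reads, and per-method observation records with dropout.

#' Generator configuration
#'
#' Bundles every tunable of the synthetic-data generators. The values that
#' come from the underlying study are the +/-0.3 degree calling window and
#' the 0.8 degree 1016I offset (both live on the assay definitions), the
#' quality threshold 10, the 100x coverage rule and the 37-base/95%
#' barcode filter (stage parameters); everything here is a fixture constant
#' chosen to be realistic for SYBR melt curves and Nanopore-like amplicon
#' reads.
#'
#' @param tm_noise_sd Sd of the per-run jitter on peak centers, degrees C.
#' @param peak_width_sd Gaussian peak width (sd), degrees C. 0.25 keeps the
#'   two non-G products (0.8 degrees apart) bimodal in a heterozygote.
#' @param height_jitter Relative peak-height jitter (uniform +/- fraction).
#' @param curve_noise_sd Sd of additive white noise on the derivative.
#' @param grid_min,grid_max,grid_step Temperature grid, degrees C.
#' @param dropout Named list of per-method dropout probabilities:
#'   `mca_class` (a detected class vanishes; either a scalar or a named
#'   per-class vector such as `c(Gclass = 1)` to reproduce a
#'   class-specific failure), `mca`, `aspcr_band`, `sanger`, `ngs`, `coi`
#'   (whole-method no-calls). All default to 0.
#' @param sub_rate,ins_rate,del_rate Per-base read error rates.
#' @param coverage Reads per amplicon per sample.
#' @param base_q_mean,base_q_sd Per-base Phred quality distribution.
#' @param barcode_error Substitution rate inside the barcode flanks.
#' @param p_p_given_g Probability that a 1016G haplotype also carries 989P.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(tm_noise_sd = 0.1, peak_width_sd = 0.25,
                             height_jitter = 0.2, curve_noise_sd = 0.005,
                             grid_min = 70, grid_max = 95, grid_step = 0.05,
                             dropout = list(), sub_rate = 0.05,
                             ins_rate = 0.005, del_rate = 0.005,
                             coverage = 200L, base_q_mean = 13,
                             base_q_sd = 3, barcode_error = 0.01,
                             p_p_given_g = 0.5) {
  d <- list(mca_class = 0, mca = 0, aspcr_band = 0, sanger = 0, ngs = 0,
            coi = 0)
  d[names(dropout)] <- dropout
  probs <- c(unlist(d, use.names = FALSE), sub_rate, ins_rate, del_rate,
             barcode_error, p_p_given_g)
  stopifnot(all(probs >= 0 & probs <= 1), coverage >= 0,
            grid_step > 0, grid_max > grid_min)
  structure(list(tm_noise_sd = tm_noise_sd, peak_width_sd = peak_width_sd,
                 height_jitter = height_jitter,
                 curve_noise_sd = curve_noise_sd, grid_min = grid_min,
                 grid_max = grid_max, grid_step = grid_step, dropout = d,
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, coverage = as.integer(coverage),
                 base_q_mean = base_q_mean, base_q_sd = base_q_sd,
                 barcode_error = barcode_error, p_p_given_g = p_p_given_g),
            class = "generator_config")
}

#' Simulate a derivative melt curve for a genotype
#'
#' One Gaussian peak per distinct product Tm class implied by the assay's
#' allele-to-Tm-class map (two alleles sharing a product give a single
#' peak). Peak centers are jittered by `tm_noise_sd`, heights are 1.0 with
#' `height_jitter` relative jitter, white noise is added and the curve is
#' clamped nonnegative. A detected class vanishes with probability
#' `dropout$mca_class`, emulating the failure mode seen in heterozygous
#' controls.
#'
#' @param assay An [assay_definition()].
#' @param genotype Length-2 allele vector at the assay's locus.
#' @param cfg A [generator_config()].
#' @param seed Integer seed.
#' @return A [melt_curve()].
#' @export
gen_melt_curve <- function(assay, genotype, cfg = generator_config(),
                           seed = 1L) {
  stopifnot(inherits(assay, "assay_definition"), length(genotype) == 2L)
  set.seed(seed)
  tt <- seq(cfg$grid_min, cfg$grid_max, by = cfg$grid_step)
  y <- numeric(length(tt))
  tm_classes <- unique(unname(assay$allele_tm_class[genotype]))
  if (anyNA(tm_classes))
    stop("genotype contains alleles unknown to assay ", assay$assay_id)
  for (cl in tm_classes) {
    obs_cl <- unname(assay$class_map[[cl]])
    if (stats::runif(1) < class_dropout_prob(cfg, obs_cl, cl)) next
    center <- assay$class_tms[[cl]] + stats::rnorm(1, 0, cfg$tm_noise_sd)
    height <- 1 * (1 + stats::runif(1, -cfg$height_jitter, cfg$height_jitter))
    y <- y + height * exp(-0.5 * ((tt - center) / cfg$peak_width_sd)^2)
  }
  y <- pmax(0, y + stats::rnorm(length(tt), 0, cfg$curve_noise_sd))
  melt_curve(tt, y)
}

#' Simulate a diploid cohort with kdr haplotype linkage
#'
#' Samples individuals at Hardy-Weinberg proportions. In linkage mode (the
#' default, reflecting the strong unidirectional linkage of 1016I with
#' 1534C and of 1016G with 1534F, and of 989P occurring only on 1016G
#' backgrounds), haplotypes rather than independent alleles are sampled, so
#' every G allele sits on an F background and every I allele on a C
#' background. The haplotype frequencies are derived from the per-locus
#' allele frequencies:
#' P-G-F = f(P); S-G-F = f(G) - f(P); S-I-C = f(I); S-V-C = f(C) - f(I);
#' S-V-F = the remainder. Frequencies violating the linkage constraints
#' (f(P) > f(G), f(I) > f(C), f(G) > f(F)) are an error.
#'
#' @param n Cohort size.
#' @param freqs Named list of per-locus allele frequency vectors, each
#'   summing to 1 (see [default_cohort_freqs()]).
#' @param cfg A [generator_config()] (used for `p_p_given_g` when `freqs`
#'   lacks an explicit 989 entry).
#' @param seed Integer seed.
#' @param linkage Sample linked haplotypes (default) or independent loci.
#' @return List of `n` [multilocus_genotype()] objects.
#' @export
gen_cohort <- function(n, freqs = default_cohort_freqs(),
                       cfg = generator_config(), seed = 1L, linkage = TRUE) {
  stopifnot(n >= 1L)
  for (lname in names(freqs)) {
    if (abs(sum(freqs[[lname]]) - 1) > 1e-8)
      stop("allele frequencies at locus ", lname, " must sum to 1")
    if (any(freqs[[lname]] < 0)) stop("negative frequency at locus ", lname)
  }
  set.seed(seed)
  gf <- function(locus, allele) {
    v <- freqs[[locus]]
    if (allele %in% names(v)) unname(v[[allele]]) else 0
  }
  if (linkage) {
    f_G <- gf("1016", "G"); f_I <- gf("1016", "I")
    f_C <- gf("1534", "C"); f_F <- gf("1534", "F")
    f_P <- if (!is.null(freqs[["989"]])) gf("989", "P")
           else cfg$p_p_given_g * f_G
    hap <- c(PGF = f_P, SGF = f_G - f_P, SIC = f_I, SVC = f_C - f_I,
             SVF = 1 - f_G - f_C)
    if (any(hap < -1e-9))
      stop("allele frequencies violate the linkage constraints ",
           "(need f(P) <= f(G), f(I) <= f(C), f(G) <= f(F))")
    hap <- pmax(hap, 0)
    hmat <- rbind(PGF = c("P", "G", "F"), SGF = c("S", "G", "F"),
                  SIC = c("S", "I", "C"), SVC = c("S", "V", "C"),
                  SVF = c("S", "V", "F"))
    idx <- sample(nrow(hmat), 2L * n, replace = TRUE, prob = hap)
    h1 <- hmat[idx[seq_len(n)], , drop = FALSE]
    h2 <- hmat[idx[n + seq_len(n)], , drop = FALSE]
    lapply(seq_len(n), function(i)
      multilocus_genotype(g1016 = c(h1[i, 2], h2[i, 2]),
                          g1534 = c(h1[i, 3], h2[i, 3]),
                          g989 = c(h1[i, 1], h2[i, 1])))
  } else {
    draw <- function(locus) {
      v <- freqs[[locus]]
      matrix(sample(names(v), 2L * n, replace = TRUE, prob = v), ncol = 2L)
    }
    a989 <- draw("989"); a1016 <- draw("1016"); a1534 <- draw("1534")
    lapply(seq_len(n), function(i)
      multilocus_genotype(g1016 = a1016[i, ], g1534 = a1534[i, ],
                          g989 = a989[i, ]))
  }
}

#' Default cohort allele frequencies
#'
#' Chosen to resemble a contemporary Florida *Ae. aegypti* population in
#' which 1016I/1534C is near fixation and the Indopacific alleles are rare
#' recent arrivals: f(I) = 0.85, f(G) = 0.036, f(C) = 0.96, f(P) = 0.018
#' (half of G haplotypes carry P).
#'
#' @return Named list of per-locus frequency vectors.
#' @export
default_cohort_freqs <- function() {
  list("989" = c(S = 0.982, P = 0.018),
       "1016" = c(V = 0.114, I = 0.85, G = 0.036),
       "1534" = c(F = 0.04, C = 0.96))
}

# dropout probability for a detected class: a named per-class entry (by
# interpretive or Tm class name) wins over the unnamed scalar default
class_dropout_prob <- function(cfg, obs_class, tm_class = obs_class) {
  p <- cfg$dropout$mca_class
  if (is.null(names(p))) return(p[[1]])
  if (tm_class %in% names(p)) return(unname(p[[tm_class]]))
  if (obs_class %in% names(p)) return(unname(p[[obs_class]]))
  0
}

# apply substitutions/insertions/deletions to a character vector of bases
mutate_bases <- function(v, sub_rate, ins_rate, del_rate) {
  n <- length(v)
  bases <- c("A", "C", "G", "T")
  sub_idx <- which(stats::runif(n) < sub_rate)
  for (i in sub_idx) v[i] <- sample(setdiff(bases, v[i]), 1L)
  if (del_rate > 0) {
    keep <- stats::runif(length(v)) >= del_rate
    v <- v[keep]
  }
  if (ins_rate > 0) {
    ins_at <- which(stats::runif(length(v)) < ins_rate)
    if (length(ins_at)) {
      # interleave by fractional positions: an insertion lands just after
      # its anchor base
      pos <- c(seq_along(v), ins_at + 0.5)
      v <- c(v, sample(bases, length(ins_at), replace = TRUE))[order(pos)]
    }
  }
  v
}

phred_string <- function(n, mean_q, sd_q) {
  q <- round(stats::rnorm(n, mean_q, sd_q))
  q <- pmin(pmax(q, 2L), 41L)
  intToUtf8(q + 33L, multiple = FALSE)
}

#' Simulate barcoded diploid amplicon reads for one sample
#'
#' For each of the four amplicons, `cfg$coverage` full-length reads are
#' drawn, each from one of the sample's two haplotypes (fair binomial; the
#' kdr codon of the drawn haplotype's allele is substituted into the
#' amplicon template). Substitution/insertion/deletion errors are injected
#' at the configured rates, the sample's barcode region is attached at both
#' ends (forward at the head, reverse-complement at the tail, with
#' `barcode_error` substitutions), the read strand is random, and the
#' quality string is drawn to be consistent with the error load.
#'
#' @param genotype A [multilocus_genotype()] (989 must be present).
#' @param panel A `reference_panel`.
#' @param barcode_seq The sample's barcode region sequence.
#' @param cfg A [generator_config()].
#' @param seed Integer seed.
#' @param sample_id Prefix for read identifiers.
#' @param coverage Optional named per-amplicon coverage override (e.g.
#'   `c(M1 = 50)`); unnamed scalar applies to all.
#' @return A `read_set` data.frame.
#' @export
gen_reads <- function(genotype, panel, barcode_seq,
                      cfg = generator_config(), seed = 1L,
                      sample_id = "sample", coverage = NULL) {
  stopifnot(inherits(genotype, "multilocus_genotype"),
            !is.null(genotype[["989"]]))
  set.seed(seed)
  cov <- stats::setNames(rep(cfg$coverage, 4L), names(panel$amplicons))
  if (!is.null(coverage)) {
    if (is.null(names(coverage))) cov[] <- coverage
    else cov[names(coverage)] <- coverage
  }
  allele_codon <- lapply(panel$codon_tables, function(tab)
    stats::setNames(names(tab), unname(tab)))
  rows <- vector("list", sum(cov))
  ri <- 0L
  for (amp in names(panel$amplicons)) {
    tmpl <- panel$amplicons[[amp]]
    locus <- names(panel$locus_amplicon)[panel$locus_amplicon == amp]
    # the two per-amplicon haplotype templates, pre-split to base vectors
    haps <- if (length(locus)) {
      cs <- panel$codon_start[[locus]]
      lapply(genotype[[locus]], function(a) {
        strsplit(paste0(substr(tmpl, 1L, cs - 1L),
                        allele_codon[[locus]][[a]],
                        substr(tmpl, cs + 3L, nchar(tmpl))), "")[[1]]
      })
    } else list(strsplit(tmpl, "")[[1]], strsplit(tmpl, "")[[1]])
    bc_f_v <- strsplit(barcode_seq, "")[[1]]
    bc_r_v <- strsplit(revcomp(barcode_seq), "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    for (i in seq_len(cov[[amp]])) {
      core <- mutate_bases(haps[[sample(2L, 1L)]], cfg$sub_rate,
                           cfg$ins_rate, cfg$del_rate)
      bc_f <- mutate_bases(bc_f_v, cfg$barcode_error, 0, 0)
      bc_r <- mutate_bases(bc_r_v, cfg$barcode_error, 0, 0)
      v <- c(bc_f, core, bc_r)
      if (stats::runif(1) < 0.5) v <- unname(rev(comp[v]))
      ri <- ri + 1L
      rows[[ri]] <- c(sprintf("%s_%s_r%04d", sample_id, amp, i),
                      paste(v, collapse = ""))
    }
  }
  mat <- do.call(rbind, rows[seq_len(ri)])
  out <- data.frame(read_id = mat[, 1], bases = mat[, 2],
                    quals = vapply(nchar(mat[, 2]), phred_string,
                                   character(1), mean_q = cfg$base_q_mean,
                                   sd_q = cfg$base_q_sd),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

#' Simulate one sample's multi-method observation record
#'
#' Pushes the true genotype through the virtual assay models to produce the
#' MCA, AS-PCR, Sanger and amplicon-sequencing cells of a record row, with
#' per-method dropout, so resolution and concordance logic can be tested
#' against known truth. The MCA cell is the analyst's joint interpretation
#' of the (post-dropout) V1016I and V1016G class sets together with the
#' F1534C assay; if the post-dropout classes do not pin down a unique 1016
#' genotype the cell is a no-call.
#'
#' @param genotype A [multilocus_genotype()].
#' @param cfg A [generator_config()].
#' @param seed Integer seed.
#' @param site Site label for the record.
#' @param sample_id Optional identifier.
#' @param models Virtual assay model list.
#' @param assays Assay definition list (for the 1534 class structure).
#' @return A one-row `kdr_records` data.frame.
#' @export
gen_observations <- function(genotype, cfg = generator_config(), seed = 1L,
                             site = "Synthetic", sample_id = NULL,
                             models = virtual_assay_models(),
                             assays = default_assay_definitions()) {
  stopifnot(inherits(genotype, "multilocus_genotype"))
  set.seed(seed)
  g1016 <- genotype[["1016"]]; g1534 <- genotype[["1534"]]
  drop_classes <- function(classes)
    classes[vapply(classes, function(cl)
      stats::runif(1) >= class_dropout_prob(cfg, cl), logical(1))]

  mca_cell <- "no call"
  if (stats::runif(1) >= cfg$dropout$mca) {
    obs <- list()
    for (aid in c("V1016I_MCA", "V1016G_MCA")) {
      cl <- drop_classes(predict_assay_outcome(g1016, models[[aid]]))
      if (length(cl)) obs <- c(obs, list(mca_observation(aid, cl)))
    }
    res <- if (length(obs)) resolve_1016(obs, models = models) else NULL
    cl1534 <- drop_classes(expected_classes(assays$F1534C_MCA, g1534))
    g1534_str <- if (length(cl1534) == 2L) "FC"
                 else if (identical(cl1534, "Fclass")) "FF"
                 else if (identical(cl1534, "Cclass")) "CC"
                 else NA_character_
    if (!is.null(res) && res$status == "resolved" && !is.na(g1534_str))
      mca_cell <- paste0(res$candidates, g1534_str)
  }

  band_V <- if ("V" %in% g1016) "strong" else if ("I" %in% g1016) "weak"
            else "absent"
  band_G <- if ("G" %in% g1016) "strong" else "absent"
  if (band_V != "absent" && stats::runif(1) < cfg$dropout$aspcr_band)
    band_V <- "absent"
  if (band_G != "absent" && stats::runif(1) < cfg$dropout$aspcr_band)
    band_G <- "absent"
  aspcr_cell <- format_aspcr(aspcr_observation(band_V, band_G))

  sanger_cell <- if (stats::runif(1) < cfg$dropout$sanger) "no call"
                 else paste(g1016, collapse = "")
  ngs_cell <- if (stats::runif(1) < cfg$dropout$ngs || is.null(genotype[["989"]]))
                "no call" else format_shorthand(genotype)
  coi_cell <- if (stats::runif(1) < cfg$dropout$coi) "no call"
              else sprintf("%s-%.2f%%",
                           sample(c("MN299016.1", "MK300224.1",
                                    "PP902511.1"), 1L),
                           stats::runif(1, 99.3, 100))
  as_kdr_records(site = site, mca = mca_cell, aspcr = aspcr_cell,
                 sanger = sanger_cell, ngs = ngs_cell, coi = coi_cell,
                 sample_id = sample_id)
}

#' Simulate a full study into an output directory
#'
#' Convenience wrapper for the command-line `simulate` entry point: draws a
#' cohort, writes per-sample observation records (TSV), the run's melt
#' curves for the 1016 assays (long CSV), barcoded FASTQ reads, the panel
#' FASTA/JSON, the barcode table and a truth table.
#'
#' @param n Cohort size.
#' @param out_dir Output directory (created if needed).
#' @param cfg A [generator_config()].
#' @param seed Integer seed.
#' @param freqs Cohort allele frequencies.
#' @return Invisibly, the truth data.frame.
#' @export
simulate_run <- function(n, out_dir, cfg = generator_config(), seed = 1L,
                         freqs = default_cohort_freqs()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- gen_cohort(n, freqs = freqs, cfg = cfg, seed = seed)
  panel <- build_reference_panel()
  barcodes <- make_barcodes(n)
  assays <- default_assay_definitions()

  truth <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    barcode_id = barcodes$barcode_id,
    genotype = vapply(cohort, format_shorthand, character(1)),
    stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(n), function(i)
    gen_observations(cohort[[i]], cfg = cfg, seed = seed + i,
                     sample_id = truth$sample_id[i])))
  class(recs) <- c("kdr_records", "data.frame")
  curves <- list()
  for (i in seq_len(n)) {
    curves[[truth$sample_id[i]]] <- list(
      V1016I_MCA = gen_melt_curve(assays$V1016I_MCA, cohort[[i]][["1016"]],
                                  cfg, seed = seed + 1000L + i),
      V1016G_MCA = gen_melt_curve(assays$V1016G_MCA, cohort[[i]][["1016"]],
                                  cfg, seed = seed + 2000L + i))
  }
  all_reads <- do.call(rbind, lapply(seq_len(n), function(i)
    gen_reads(cohort[[i]], panel, barcodes$sequence[i], cfg,
              seed = seed + 3000L + i, sample_id = truth$sample_id[i])))
  class(all_reads) <- c("read_set", "data.frame")

  write_records_tsv(recs, file.path(out_dir, "records.tsv"))
  write_curves_csv(curves, file.path(out_dir, "curves.csv"))
  write_fastq(all_reads, file.path(out_dir, "reads.fastq"))
  write_panel(panel, file.path(out_dir, "panel.fasta"),
              file.path(out_dir, "panel.json"))
  utils::write.table(barcodes, file.path(out_dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(truth)
}
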