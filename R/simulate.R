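#' Default 20-marker B-cell panel
#'
#' The marker panel used throughout the package: the B-cell lineage,
#' maturation and activation markers that define the classical subsets
#' (transitional, naive, memory, plasmablast) together with the eight
#' cluster-defining markers of the disease-associated subpopulation (CD20,
#' CD268, CD5, CD27, CD38, CD86, CD269, CD319). Slots beyond the named core
#' (CD21, CD24, CD138, IgG, HLADR, CD95, CD71, CD10, CXCR5) are placeholder
#' lineage/activation markers standing in for an instrument panel whose full
#' identity is not public; they carry signal in the simulator but nothing in
#' the pipeline depends on their names.
#'
#' @return Character vector of 20 marker names.
#' @export
#' @examples
#' default_panel()
default_panel <- function() {
  c("CD19", "CD20", "CD21", "CD24", "CD27", "CD38", "CD5", "CD86",
    "CD138", "CD268", "CD269", "CD319", "IgD", "IgM", "IgG", "HLADR",
    "CD95", "CD71", "CD10", "CXCR5")
}

# intensity levels on the arcsinh axis shared by all templates
.lv <- c(neglo = 0.2, neg = 0.5, dim = 1.5, pos = 3.0, hi = 3.5, vhi = 4.0)

#' B-cell subpopulation templates
#'
#' Location model for each simulated B-cell subpopulation: one mean
#' intensity per marker on the arcsinh-transformed axis (negative around
#' 0.5, positive around 3, high 3.5--4; Gaussian noise is added at
#' generation time). Besides the classical subsets, the table contains the
#' planted disease subpopulation (plasmablast-like,
#' CD19+CD20-CD27+CD38hi CD86+ IgD-) and three disease-independent
#' "confounder" populations that each match the disease phenotype on all
#' candidate markers but one: the conventional plasmablast (CD86-), a
#' CD20+ activated B cell, and a CD27- plasmablast. Their presence makes
#' CD20, CD27 and CD86 jointly -- and only jointly -- sufficient to isolate
#' the disease subset, so minimal-panel recovery is a property of the
#' simulated biology, not of the code under test.
#'
#' @param panel marker names; must be `default_panel()` order-compatible.
#' @return Tibble: `template`, `baseline_fraction`, then one column per
#'   marker with the location of that template on the transformed axis.
#'   Baseline fractions sum to 1.
#' @export
bcell_templates <- function(panel = default_panel()) {
  l <- .lv
  base <- function(...) {
    v <- c(...)
    stopifnot(length(v) == 20)
    setNames(v, default_panel())
  }
  #            CD19     CD20     CD21    CD24    CD27   CD38    CD5     CD86    CD138  CD268    CD269   CD319   IgD     IgM     IgG     HLADR   CD95    CD71    CD10    CXCR5
  naive <- base(l["pos"], l["pos"], l["pos"], l["pos"], l["neg"], l["neg"], l["neg"], l["neg"], l["neg"], l["pos"], l["neg"], l["neg"], l["pos"], l["pos"], l["neg"], l["pos"], l["neg"], l["neg"], l["neg"], l["pos"])
  memory <- naive
  memory[c("CD27", "IgD", "IgM", "IgG", "CD95")] <- c(l["pos"], l["neg"], l["neg"], l["pos"], l["pos"])
  transitional <- naive
  transitional[c("CD24", "CD38", "CD10", "CD21", "CD5", "CD71", "IgM")] <-
    c(l["vhi"], l["vhi"], l["pos"], l["dim"], l["dim"], l["dim"], l["hi"])
  b1like <- naive
  b1like[c("CD5", "CD27", "IgM")] <- c(l["pos"], l["pos"], l["pos"])
  disease <- base(l["pos"], l["neglo"], l["neg"], l["neg"], l["hi"], l["vhi"], l["hi"], l["hi"], l["dim"], l["neglo"], l["hi"], l["hi"], l["neg"], l["neg"], l["dim"], l["pos"], l["dim"], l["dim"], l["neg"], l["neg"])
  plasmablast <- disease                       # CD86- flip
  plasmablast[c("CD86", "CD138", "HLADR")] <- c(l["neg"], l["pos"], l["dim"])
  activated_b <- disease                       # CD20+ flip
  activated_b[c("CD20", "CD21", "CD24", "CD95")] <- c(l["pos"], l["pos"], l["pos"], l["pos"])
  early_pb <- disease                          # CD27- flip
  early_pb[c("CD27", "IgM", "CD71")] <- c(l["neg"], l["pos"], l["pos"])

  prof <- rbind(naive = naive, memory = memory, transitional = transitional,
                b1like = b1like, plasmablast = plasmablast,
                activated_b = activated_b, early_pb = early_pb,
                disease = disease)
  missing_mk <- setdiff(panel, colnames(prof))
  if (length(missing_mk) > 0) {
    abort(paste0("no template profile for marker(s): ",
                 paste(missing_mk, collapse = ", ")))
  }
  out <- tibble(
    template = rownames(prof),
    baseline_fraction = c(0.637, 0.20, 0.08, 0.03, 0.015, 0.02, 0.008, 0.01)
  )
  stopifnot(abs(sum(out$baseline_fraction) - 1) < 1e-9)
  dplyr::bind_cols(out, as_tibble(prof[, panel, drop = FALSE]))
}

.strata <- c("HD", "nonGVHD_stable", "nonGVHD_active", "cGVHD_nonDP", "cGVHD_DP")

.group_of <- function(stratum) {
  dplyr::case_when(
    stratum == "HD" ~ "HD",
    startsWith(stratum, "nonGVHD") ~ "nonGVHD",
    startsWith(stratum, "cGVHD") ~ "cGVHD"
  )
}

#' Simulation configuration
#'
#' Validated parameter block for [generate_cohort()]. Defaults emulate the
#' study design: five frequency strata whose planted disease-subset
#' frequency means (HD 0.3, non-GVHD stable 0.6 / active 2.0, cGVHD non-DP
#' 1.0 / DP 3.0, percent of B cells) straddle the decision boundaries 1.15
#' and 1.51 used to assign outcome labels; a two-institute additive batch
#' shift; and Beta-distributed per-subject frequencies whose spread is
#' calibrated so cohort-level separation matches the discrimination the
#' score achieves in practice (subject-level AUC around 0.95).
#'
#' @param n_subjects named integer vector of subjects per stratum. Allowed
#'   names: `r paste(.strata, collapse = ", ")`. Strata can be omitted, but a
#'   listed stratum must have a positive count.
#' @param cells_per_subject cells drawn per subject.
#' @param panel marker names (see [default_panel()]).
#' @param disease_freq tibble with columns `stratum`, `mean`, `kappa`:
#'   per-stratum Beta distribution of the planted frequency (percent of B
#'   cells; `kappa` is the Beta precision, `Inf` for a degenerate
#'   point-mass).
#' @param confounder_freq named list of `c(mean, kappa)` (percent) for the
#'   three disease-independent confounder populations.
#' @param noise_sd Gaussian intensity noise around each template location.
#' @param batch_shift_sd scale of the per-batch additive marker shift on the
#'   transformed axis.
#' @param n_batches number of batches (institutes); subjects are assigned
#'   round-robin within stratum.
#' @param outcome_label_noise probability in \[0, 0.5) of flipping a
#'   subject's outcome label away from its frequency-determined value.
#' @param boundaries named vector: the planted frequency above which a
#'   non-GVHD subject is labelled `active` and a cGVHD subject `DP`.
#' @param cofactor arcsinh cofactor used to put generated intensities back
#'   on the raw fluorescence scale.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config including this seed.
#' @return A `cgps_sim_config` list.
#' @export
sim_config <- function(n_subjects = c(HD = 17, nonGVHD_stable = 10,
                                      nonGVHD_active = 5, cGVHD_nonDP = 21,
                                      cGVHD_DP = 10),
                       cells_per_subject = 2000,
                       panel = default_panel(),
                       disease_freq = default_disease_freq(),
                       confounder_freq = list(
                         plasmablast = c(mean = 3.0, kappa = 70),
                         activated_b = c(mean = 3.5, kappa = 70),
                         early_pb    = c(mean = 2.5, kappa = 70)),
                       noise_sd = 0.4,
                       batch_shift_sd = 0.2,
                       n_batches = 2,
                       outcome_label_noise = 0,
                       boundaries = c(nonGVHD = 1.15, cGVHD = 1.51),
                       cofactor = 150,
                       seed = 1) {
  bad <- setdiff(names(n_subjects), .strata)
  if (length(bad) > 0) abort(paste0("unknown stratum: ", paste(bad, collapse = ", ")))
  nonpos <- names(n_subjects)[n_subjects <= 0]
  if (length(nonpos) > 0) {
    abort(paste0("stratum with zero subjects: ", paste(nonpos, collapse = ", "),
                 " (omit the stratum instead of listing it with count 0)"))
  }
  if (cells_per_subject <= 0) abort("cells_per_subject must be positive")
  if (outcome_label_noise < 0 || outcome_label_noise >= 0.5) {
    abort("outcome_label_noise must be in [0, 0.5)")
  }
  if (any(disease_freq$mean < 0 | disease_freq$mean > 100)) {
    abort("disease frequency means must lie in [0, 100] percent")
  }
  missing_st <- setdiff(names(n_subjects), disease_freq$stratum)
  if (length(missing_st) > 0) {
    abort(paste0("no disease frequency distribution for stratum: ",
                 paste(missing_st, collapse = ", ")))
  }
  structure(
    list(n_subjects = n_subjects, cells_per_subject = cells_per_subject,
         panel = panel, disease_freq = disease_freq,
         confounder_freq = confounder_freq, noise_sd = noise_sd,
         batch_shift_sd = batch_shift_sd, n_batches = n_batches,
         outcome_label_noise = outcome_label_noise, boundaries = boundaries,
         cofactor = cofactor, seed = as.integer(seed)),
    class = "cgps_sim_config"
  )
}

#' @rdname sim_config
#' @export
default_disease_freq <- function() {
  tibble(stratum = .strata,
         mean = c(0.3, 0.6, 2.0, 1.0, 3.0),
         kappa = 3000)
}

# one Beta draw on the percent scale; kappa = Inf gives the point mass
.draw_freq <- function(n, mean_pct, kappa) {
  m <- mean_pct / 100
  if (is.infinite(kappa) || m <= 0 || m >= 1) return(rep(m * 100, n))
  100 * rbeta(n, m * kappa, (1 - m) * kappa)
}

#' Generate a synthetic cytometry cohort
#'
#' Draws a cohort of single-B-cell marker-expression samples with a planted
#' disease-associated subpopulation. Per subject: the planted frequency is
#' drawn from its stratum's Beta distribution, confounder-population
#' frequencies from their own (disease-independent) distributions, cell
#' counts per subpopulation multinomially, and cell intensities from each
#' template's Gaussian location model on the arcsinh axis; the subject's
#' batch shift is added and values are returned on the raw fluorescence
#' scale (`sinh(v) * cofactor`). Outcome labels are a deterministic function
#' of the planted frequency (above/below the configured boundary), flipped
#' with probability `outcome_label_noise`. Every diseased subject's
#' CD19+CD20- compartment is kept above 1% of B cells, matching the
#' observation that motivates the denominator choice of the score.
#'
#' The cohort is bit-identical across runs for an identical config.
#'
#' @param config a [sim_config()].
#' @return A [new_cohort()] with ground truth: cells carry a `.template`
#'   column, subjects a `truth_freq` column (planted frequency, percent).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cgps_sim_config"))
  set.seed(config$seed)
  tmpl <- bcell_templates(config$panel)
  prof <- as.matrix(tmpl[, config$panel])
  rownames(prof) <- tmpl$template
  classical <- c("naive", "memory", "transitional", "b1like")
  conf_names <- names(config$confounder_freq)

  batch_shift <- matrix(
    rnorm(config$n_batches * length(config$panel), 0, config$batch_shift_sd),
    nrow = config$n_batches,
    dimnames = list(paste0("B", seq_len(config$n_batches)), config$panel)
  )

  subjects <- list(); cells <- list()
  for (stratum in intersect(.strata, names(config$n_subjects))) {
    n_sub <- config$n_subjects[[stratum]]
    dfq <- config$disease_freq[config$disease_freq$stratum == stratum, ]
    group <- .group_of(stratum)
    for (i in seq_len(n_sub)) {
      sid <- sprintf("%s_%02d", stratum, i)
      batch <- paste0("B", ((i - 1L) %% config$n_batches) + 1L)
      f_dis <- .draw_freq(1, dfq$mean, dfq$kappa)
      f_conf <- vapply(config$confounder_freq,
                       function(p) .draw_freq(1, p[["mean"]], p[["kappa"]]), 0)
      # CD19+CD20- floor for diseased subjects: disease + plasmablast + early_pb > 1%
      if (group != "HD") {
        cd20neg <- f_dis + f_conf[["plasmablast"]] + f_conf[["early_pb"]]
        if (cd20neg <= 1.0) {
          f_conf[["plasmablast"]] <- f_conf[["plasmablast"]] + (1.05 - cd20neg)
        }
      }
      frac <- setNames(numeric(nrow(tmpl)), tmpl$template)
      frac["disease"] <- f_dis / 100
      frac[conf_names] <- f_conf / 100
      rest <- 1 - sum(frac)
      base_cl <- tmpl$baseline_fraction[match(classical, tmpl$template)]
      frac[classical] <- rest * base_cl / sum(base_cl)
      counts <- rmultinom(1, config$cells_per_subject, frac)[, 1]
      template_of <- rep(names(counts), counts)
      v <- prof[template_of, , drop = FALSE] +
        matrix(rnorm(length(template_of) * ncol(prof), 0, config$noise_sd),
               ncol = ncol(prof))
      v <- sweep(v, 2, batch_shift[batch, ], "+")
      raw <- sinh(v) * config$cofactor
      cells[[sid]] <- dplyr::bind_cols(
        tibble(subject_id = sid, .template = template_of),
        as_tibble(raw)
      )
      outcome <- NA_character_
      if (group == "nonGVHD") {
        active <- f_dis > config$boundaries[["nonGVHD"]]
        if (runif(1) < config$outcome_label_noise) active <- !active
        outcome <- if (active) "active" else "stable"
      } else if (group == "cGVHD") {
        dp <- f_dis > config$boundaries[["cGVHD"]]
        if (runif(1) < config$outcome_label_noise) dp <- !dp
        outcome <- if (dp) "DP" else sample(c("PR", "CR", "SD"), 1)
      }
      subjects[[sid]] <- tibble(
        subject_id = sid, group = group, stratum = stratum, batch = batch,
        outcome = outcome, truth_freq = f_dis
      )
    }
  }
  new_cohort(
    cells = bind_rows(cells), subjects = bind_rows(subjects),
    markers = config$panel, transformed = FALSE, scaled = FALSE
  )
}
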