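# Seeded Monte-Carlo cohort simulator: uniform age and diet, Bernoulli 0/1
# marker activation at (diet-modified) Table-1 priors, derived fusion/fission
# flags and a deterministic AD-progression probability per patient.
#
# RNG contract: one seeded generator per cohort; exactly 14 uniform draws per
# patient, consumed in the order (age, diet, markers in cohort column order).
# simulate_cohort() vectorises this by reshaping a single runif(n * 14) in
# patient-major order, which is stream-identical to calling the per-patient
# samplers in a loop (asserted by a unit test).

.age_from_u <- function(u, lo = 30L, hi = 95L) {
  k <- hi - lo + 1L
  lo + pmin(as.integer(floor(u * k)), k - 1L)
}

.diet_from_u <- function(u, diets) {
  k <- length(diets)
  diets[1L + pmin(as.integer(floor(u * k)), k - 1L)]
}

#' Apply an odds-scale modifier to a probability
#'
#' `p` is mapped through odds: `m * p/(1-p) / (1 + m * p/(1-p))`. The
#' endpoints 0 and 1 are fixed points for every modifier.
#'
#' @param p Probability (vectorised).
#' @param m Positive odds multiplier.
#' @return Modified probability in \[0, 1\].
#' @export
apply_odds_modifier <- function(p, m) {
  stopifnot(all(m > 0))
  ifelse(p <= 0, 0, ifelse(p >= 1, 1, m * p / (1 - p + m * p)))
}

# effective Bernoulli probability for each of the 12 markers under one diet
.effective_marker_probs <- function(diet, priors, modifiers) {
  mk <- admito_markers()
  p <- vapply(mk, marker_prior, numeric(1), priors = priors)
  mods <- modifiers$modifiers[[diet]]
  if (length(mods)) {
    idx <- match(names(mods), mk)
    p[idx] <- apply_odds_modifier(p[idx], mods)
  }
  p
}

#' Sample patient ages
#'
#' Integer ages drawn uniformly (inclusive) from the configured range,
#' consuming one uniform draw per age from the current RNG stream.
#'
#' @param n Number of draws.
#' @param age_range Integer length-2 vector.
#' @return Integer vector of length `n`.
#' @export
sample_age <- function(n = 1L, age_range = c(30L, 95L)) {
  .age_from_u(stats::runif(n), age_range[[1]], age_range[[2]])
}

#' Sample diet categories
#'
#' Categories drawn uniformly over `diets`, one uniform draw per patient.
#'
#' @param n Number of draws.
#' @param diets Character vector of categories.
#' @return Character vector of length `n`.
#' @export
sample_diet <- function(n = 1L, diets = admito_diets()) {
  stopifnot(length(diets) >= 1L)
  .diet_from_u(stats::runif(n), diets)
}

#' Sample the 12 binary markers for one patient
#'
#' One independent Bernoulli draw per marker at its effective probability:
#' the Table-1 prior (or `default_prior`), pushed through the diet's
#' odds-scale modifier and clamped to \[0, 1\]. This realises the model's
#' "activation function": a marker is 1 (abnormal/positive) when its uniform
#' draw falls below the effective activation probability. Markers with a
#' CPT override in `network` are instead drawn at the override probability
#' given the already-sampled parent states (parents must precede the child
#' in the marker order).
#'
#' @param diet Diet category.
#' @param priors A [prior_table()].
#' @param modifiers A [diet_modifier_table()].
#' @param network Optional [network_spec()] carrying `cpt_overrides`.
#' @return Named integer vector over [admito_markers()], values 0/1.
#' @export
sample_markers <- function(diet, priors = default_prior_table(),
                           modifiers = default_diet_modifiers(),
                           network = NULL) {
  u <- stats::runif(length(admito_markers()))
  .markers_from_u(matrix(u, nrow = 1L), diet, priors, modifiers, network)[1L, ]
}

# vectorised marker sampling: u is an n x 12 matrix of uniform draws,
# diet a length-n character vector; returns an n x 12 0/1 integer matrix
.markers_from_u <- function(u, diet, priors, modifiers, network = NULL) {
  mk <- admito_markers()
  diets <- modifiers$diets
  pmat <- vapply(diets, .effective_marker_probs, numeric(length(mk)),
                 priors = priors, modifiers = modifiers)  # 12 x ndiet
  p <- t(pmat)[match(diet, diets), , drop = FALSE]        # n x 12
  overrides <- if (is.null(network)) list() else network$cpt_overrides
  ov_by_child <- stats::setNames(overrides,
                                 vapply(overrides, `[[`, "", "child"))
  .validate_override_order(ov_by_child, mk)
  x <- matrix(0L, nrow = nrow(u), ncol = length(mk),
              dimnames = list(NULL, mk))
  for (j in seq_along(mk)) {
    pj <- p[, j]
    ov <- ov_by_child[[mk[[j]]]]
    if (!is.null(ov)) {
      states <- x[, ov$parents, drop = FALSE]
      key <- apply(states, 1L, paste, collapse = "")
      pj <- unname(unlist(ov$probs)[key])
    }
    x[, j] <- as.integer(u[, j] < pj)
  }
  x
}

.validate_override_order <- function(ov_by_child, mk) {
  for (ov in ov_by_child) {
    if (!ov$child %in% mk) {
      stop("cpt override child '", ov$child, "' is not a simulated marker",
           call. = FALSE)
    }
    late <- setdiff(ov$parents, mk[seq_len(match(ov$child, mk) - 1L)])
    if (length(late)) {
      stop(sprintf(
        "cpt override for '%s': parent(s) %s must precede it in the marker order",
        ov$child, paste(late, collapse = ", ")), call. = FALSE)
    }
  }
}

#' Derive the mitochondrial fusion flag
#'
#' Fusion is mediated by OPA1, MFN1 and MFN2; the cohort-level flag is 1
#' iff at least two of the three fusion markers are abnormal. This is the
#' minimal monotone rule consistent with all five published example rows
#' (see the methods vignette).
#'
#' @param markers Named 0/1 vector containing at least opa1, mfn1, mfn2.
#' @return 0 or 1.
#' @export
derive_fusion <- function(markers) {
  need <- c("opa1", "mfn1", "mfn2")
  miss <- setdiff(need, names(markers))
  if (length(miss)) {
    stop("markers missing required key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  as.integer(sum(markers[need]) >= 2L)
}

#' Derive the mitochondrial fission flag
#'
#' Fission is mediated by DRP1 (recruited by FIS1); the flag is 1 iff
#' drp1 = 1 or fis1 = 1.
#'
#' @param markers Named 0/1 vector containing at least drp1, fis1.
#' @return 0 or 1.
#' @export
derive_fission <- function(markers) {
  need <- c("drp1", "fis1")
  miss <- setdiff(need, names(markers))
  if (length(miss)) {
    stop("markers missing required key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  as.integer(any(markers[need] == 1L))
}

#' Simulate a patient cohort
#'
#' Generates `n` synthetic patients: uniform integer age, uniform diet
#' category, independent Bernoulli marker activation at the (diet-modified)
#' priors, derived fusion/fission flags, and the deterministic
#' AD-progression probability from [evaluate_ad_probability()]. Fully
#' reproducible from `(n, seed, config)`.
#'
#' @param n Number of patients (>= 1).
#' @param seed Integer RNG seed.
#' @param config An `ad_config` ([default_config()] if omitted).
#' @return A `cohort_table`: a data frame with columns id, atp, opa1, mfn1,
#'   mfn2, drp1, fis1, db, os, ht, ob, dp, pa, diet, age, fusion, fission,
#'   AD, and attributes `n`, `seed`, `config_digest`.
#' @export
#' @examples
#' cohort <- simulate_cohort(100, seed = 7)
#' table(cohort$diet)
simulate_cohort <- function(n, seed = 1L, config = default_config()) {
  stopifnot(inherits(config, "ad_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  sim <- config$simulation
  nmk <- length(admito_markers())
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  u <- matrix(stats::runif(n * (2L + nmk)), nrow = n, byrow = TRUE)
  age <- .age_from_u(u[, 1L], sim$age_min, sim$age_max)
  diet <- .diet_from_u(u[, 2L], sim$diets)
  x <- .markers_from_u(u[, -(1:2), drop = FALSE], diet, config$priors,
                       config$diet_modifiers, config$network)
  fusion <- as.integer(x[, "opa1"] + x[, "mfn1"] + x[, "mfn2"] >= 2L)
  fission <- as.integer(x[, "drp1"] + x[, "fis1"] >= 1L)
  ad <- .ad_prob_vec(x, diet, age, config$priors, config$case_rule)
  cohort <- data.frame(id = seq_len(n), x, diet = diet, age = age,
                       fusion = fusion, fission = fission, AD = ad)
  as_cohort_table(cohort, n = n, seed = as.integer(seed),
                  config_digest = config_digest(config))
}

#' @rdname simulate_cohort
#' @param cohort Data frame with the 18 schema columns.
#' @param ... Metadata fields (`n`, `seed`, `config_digest`).
#' @export
as_cohort_table <- function(cohort, ...) {
  cols <- c("id", admito_markers(), "diet", "age", "fusion", "fission", "AD")
  miss <- setdiff(cols, names(cohort))
  if (length(miss)) {
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cohort <- cohort[, cols]
  meta <- list(...)
  .validate_cohort(cohort)
  structure(cohort,
            n = if (!is.null(meta$n)) meta$n else nrow(cohort),
            seed = meta$seed, config_digest = meta$config_digest,
            class = c("cohort_table", "data.frame"))
}

.validate_cohort <- function(cohort, age_range = c(30L, 95L)) {
  flags <- c(admito_markers(), "fusion", "fission")
  for (cl in flags) {
    bad <- which(!cohort[[cl]] %in% c(0L, 1L))
    if (length(bad)) {
      stop(sprintf("row %d, column '%s': flag must be 0 or 1",
                   bad[[1]], cl), call. = FALSE)
    }
  }
  bad <- which(cohort$age < age_range[[1]] | cohort$age > age_range[[2]] |
                 cohort$age != round(cohort$age))
  if (length(bad)) {
    stop(sprintf("row %d, column 'age': out of range [%d, %d]",
                 bad[[1]], age_range[[1]], age_range[[2]]), call. = FALSE)
  }
  bad <- which(!cohort$diet %in% admito_diets())
  if (length(bad)) {
    stop(sprintf("row %d, column 'diet': unknown category '%s'",
                 bad[[1]], cohort$diet[[bad[[1]]]]), call. = FALSE)
  }
  bad <- which(cohort$AD < 0 | cohort$AD > 1 | is.na(cohort$AD))
  if (length(bad)) {
    stop(sprintf("row %d, column 'AD': probability outside [0, 1]",
                 bad[[1]]), call. = FALSE)
  }
  if (!identical(as.integer(cohort$id), seq_len(nrow(cohort)))) {
    stop("cohort ids must be sequential from 1", call. = FALSE)
  }
  invisible(cohort)
}
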