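# Static model structure: prior table, signed influence graph, diet modifiers,
# configuration loading/writing and validation.

#' Marker and diet vocabularies
#'
#' `admito_markers()` returns the twelve binary biomarkers in the canonical
#' cohort-table column order; `admito_diets()` returns the five diet
#' categories (four interventions plus `"none"`, serialised as `"0"` in CSV).
#'
#' @return Character vector.
#' @export
admito_markers <- function() {
  c("atp", "opa1", "mfn1", "mfn2", "drp1", "fis1",
    "db", "os", "ht", "ob", "dp", "pa")
}

#' @rdname admito_markers
#' @export
admito_diets <- function() {
  c("HFO", "HL", "starv", "CR", "none")
}

.mito_markers <- function() c("opa1", "mfn1", "mfn2", "drp1", "fis1")

.check_prob <- function(p, what) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(sprintf("invalid probability for '%s': must be in [0, 1]", what),
         call. = FALSE)
  }
  invisible(p)
}

#' Prior probability table
#'
#' Container for the marginal prior probability of abnormality of each binary
#' biomarker and the age-bracket risk weights. The bundled default
#' ([default_prior_table()]) carries the published estimates: age brackets
#' (<65: 0.04, 65-74: 0.15, 75-84: 0.43, >=85: 0.38) and markers
#' (hypertension 0.20, oxidative stress 0.275 -- the midpoint of the
#' published 25-30% range --, obesity 0.034, depression 0.132, physical
#' activity 0.177, drp1 0.743, opa1 0.614, mfn1 0.278, mfn2 0.336,
#' fis1 0.60). Markers without a published prior (atp, db) fall back to
#' `default_prior`.
#'
#' @param marker_priors Named numeric vector, probabilities in \[0, 1\].
#' @param age_brackets Data frame with integer columns `min`, `max` and a
#'   numeric column `p`; brackets must be disjoint and jointly cover
#'   `age_range`.
#' @param default_prior Probability used for markers absent from
#'   `marker_priors` (default 0.5: an uninformative coin flip).
#' @param age_range Integer length-2 vector, the supported age range.
#' @return An object of class `prior_table`.
#' @export
prior_table <- function(marker_priors, age_brackets, default_prior = 0.5,
                        age_range = c(30L, 95L)) {
  if (is.null(names(marker_priors)) || any(names(marker_priors) == "")) {
    stop("marker_priors must be a fully named numeric vector", call. = FALSE)
  }
  for (m in names(marker_priors)) .check_prob(marker_priors[[m]], m)
  .check_prob(default_prior, "default_prior")
  stopifnot(is.data.frame(age_brackets),
            all(c("min", "max", "p") %in% names(age_brackets)))
  .check_prob(age_brackets$p, "age_brackets$p")
  ab <- age_brackets[order(age_brackets$min), , drop = FALSE]
  if (any(ab$min > ab$max)) {
    stop("age bracket with min > max", call. = FALSE)
  }
  covered <- unlist(Map(seq, ab$min, ab$max))
  want <- seq(age_range[[1]], age_range[[2]])
  if (anyDuplicated(covered) || !setequal(covered, want)) {
    stop(sprintf("age brackets must disjointly cover [%d, %d]",
                 age_range[[1]], age_range[[2]]), call. = FALSE)
  }
  structure(
    list(marker_priors = unlist(marker_priors), age_brackets = ab,
         default_prior = default_prior,
         age_range = as.integer(age_range)),
    class = "prior_table"
  )
}

#' @rdname prior_table
#' @export
default_prior_table <- function() {
  prior_table(
    marker_priors = c(
      ht = 0.20, os = 0.275, ob = 0.034, dp = 0.132, pa = 0.177,
      drp1 = 0.743, opa1 = 0.614, mfn1 = 0.278, mfn2 = 0.336, fis1 = 0.60
    ),
    age_brackets = data.frame(
      min = c(30L, 65L, 75L, 85L),
      max = c(64L, 74L, 84L, 95L),
      p   = c(0.04, 0.15, 0.43, 0.38)
    ),
    default_prior = 0.5
  )
}

#' Effective marker prior
#'
#' Looks a marker up in a [prior_table()], falling back to its
#' `default_prior` for markers without a published estimate.
#'
#' @param marker Marker name.
#' @param priors A `prior_table`.
#' @return Probability.
#' @export
marker_prior <- function(marker, priors) {
  stopifnot(inherits(priors, "prior_table"))
  if (marker %in% names(priors$marker_priors)) {
    priors$marker_priors[[marker]]
  } else {
    priors$default_prior
  }
}

#' Age-bracket risk weight
#'
#' Returns the prior AD-progression probability of the unique age bracket
#' containing `age`. Used by the case evaluator as the fallback when no
#' marker is abnormal; age itself is sampled uniformly by the simulator,
#' not from these weights.
#'
#' @param age Integer age in years, within the table's `age_range`.
#' @param priors A [prior_table()].
#' @return Probability of the bracket containing `age`.
#' @export
#' @examples
#' age_risk(63, default_prior_table())  # 0.04
#' age_risk(80, default_prior_table())  # 0.43
age_risk <- function(age, priors = default_prior_table()) {
  stopifnot(inherits(priors, "prior_table"), length(age) == 1L)
  if (!is.finite(age) || age != round(age) ||
      age < priors$age_range[[1]] || age > priors$age_range[[2]]) {
    stop(sprintf("age must be an integer in [%d, %d]",
                 priors$age_range[[1]], priors$age_range[[2]]), call. = FALSE)
  }
  ab <- priors$age_brackets
  hit <- which(ab$min <= age & age <= ab$max)
  ab$p[[hit]]
}

#' Signed influence graph
#'
#' Node set and signed directed edges of the model's acyclic influence
#' graph. Edge signs are symbolic: `"promoting"` (the parent makes the child
#' more likely) or `"deterrent"` (the parent protects against the child).
#' Quantitative effects live in the [diet_modifier_table()], not here.
#'
#' `cpt_overrides` optionally attaches a 2x2 (or 2^k) conditional
#' probability table to a marker: a list of entries
#' `list(child =, parents =, probs =)` where `probs` is named by the parent
#' state combination written as a string of 0/1 characters in parent order
#' (`"00"`, `"01"`, `"10"`, `"11"` for two parents), covering all
#' combinations.
#'
#' @param nodes Character vector of node names.
#' @param edges Data frame with character columns `parent`, `child`, `sign`.
#' @param cpt_overrides Optional list of override entries (see Details).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(nodes, edges, cpt_overrides = list()) {
  stopifnot(is.character(nodes), is.data.frame(edges),
            all(c("parent", "child", "sign") %in% names(edges)))
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  bad <- setdiff(unique(c(edges$parent, edges$child)), nodes)
  if (length(bad)) {
    stop("edge endpoint(s) not declared as nodes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(edges$sign %in% c("promoting", "deterrent"))) {
    stop("edge sign must be 'promoting' or 'deterrent'", call. = FALSE)
  }
  for (ov in cpt_overrides) {
    if (!all(c("child", "parents", "probs") %in% names(ov))) {
      stop("cpt override must have fields child, parents, probs",
           call. = FALSE)
    }
    k <- length(ov$parents)
    want <- apply(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE],
                  1L, paste, collapse = "")
    if (!setequal(names(ov$probs), want)) {
      stop(sprintf("cpt override for '%s' must enumerate all %d parent-state combinations",
                   ov$child, 2L^k), call. = FALSE)
    }
    .check_prob(unlist(ov$probs), paste0("cpt_overrides$", ov$child))
  }
  spec <- structure(list(nodes = nodes, edges = edges,
                         cpt_overrides = cpt_overrides),
                    class = "network_spec")
  validate_dag(spec)  # acyclicity is a construction invariant
  spec
}

#' @rdname network_spec
#' @export
default_network_spec <- function() {
  e <- function(parent, child, sign) data.frame(parent, child, sign)
  edges <- rbind(
    # diet shapes oxidative stress, obesity and the mitochondrial machinery
    e("diet", "os",   "deterrent"),   # fish-oil diet lowers ROS
    e("diet", "ob",   "promoting"),   # lard diet induces obesity
    e("diet", "atp",  "promoting"),
    e("diet", "opa1", "promoting"),
    e("diet", "mfn1", "promoting"),
    e("diet", "mfn2", "promoting"),
    e("diet", "drp1", "promoting"),
    e("diet", "fis1", "promoting"),
    # fusion machinery and fission machinery
    e("opa1", "fusion", "promoting"),
    e("mfn1", "fusion", "promoting"),
    e("mfn2", "fusion", "promoting"),
    e("drp1", "fission", "promoting"),
    e("fis1", "fission", "promoting"),
    # risk factors and dynamics converge on AD progression
    e("fusion",  "AD", "deterrent"),
    e("fission", "AD", "promoting"),
    e("atp", "AD", "deterrent"),
    e("db",  "AD", "promoting"),
    e("os",  "AD", "promoting"),
    e("ht",  "AD", "promoting"),
    e("ob",  "AD", "promoting"),
    e("dp",  "AD", "promoting"),
    e("pa",  "AD", "deterrent"),
    e("age", "AD", "promoting")
  )
  network_spec(
    nodes = c("age", "diet", admito_markers(), "fusion", "fission", "AD"),
    edges = edges
  )
}

#' Topologically sort an influence graph
#'
#' Kahn's algorithm; errors (listing one cycle) if the graph is cyclic.
#'
#' @param spec A [network_spec()], or any list with `nodes` and `edges`
#'   fields of the same shape.
#' @return Character vector: a node ordering in which every parent precedes
#'   its children.
#' @export
validate_dag <- function(spec) {
  nodes <- spec$nodes
  edges <- spec$edges
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(edges$child)
    indeg[names(tab)] <- as.integer(tab)
  }
  order <- character(0)
  avail <- names(indeg)[indeg == 0L]
  remaining <- edges
  while (length(avail)) {
    n <- avail[[1L]]
    avail <- avail[-1L]
    order <- c(order, n)
    out <- remaining$parent == n
    for (ch in remaining$child[out]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) avail <- c(avail, ch)
    }
    remaining <- remaining[!out, , drop = FALSE]
  }
  if (length(order) < length(nodes)) {
    cyc <- .find_cycle(setdiff(nodes, order), edges)
    stop("graph is cyclic: ", paste(cyc, collapse = " -> "), call. = FALSE)
  }
  order
}

# walk forward among the unsortable nodes until a node repeats
.find_cycle <- function(stuck, edges) {
  cur <- stuck[[1L]]
  path <- cur
  repeat {
    nxt <- edges$child[edges$parent == cur & edges$child %in% stuck][1L]
    if (nxt %in% path) return(c(path[which(path == nxt):length(path)], nxt))
    path <- c(path, nxt)
    cur <- nxt
  }
}

#' Diet modifier table
#'
#' Per-diet, per-marker odds-scale multipliers applied to the marginal
#' marker priors during simulation: a marker with prior `p` under modifier
#' `m` is drawn with probability `m*p/(1-p) / (1 + m*p/(1-p))`. A modifier
#' of 1 is the identity; the `"none"` diet is all-identity. The published
#' model gives edge signs but no magnitudes, so the bundled defaults use
#' symmetric placeholders: 2.0 for risk-promoting diet effects and 0.5 for
#' protective ones (see the methods vignette).
#'
#' @param modifiers Named list: diet category -> named numeric vector of
#'   odds multipliers (missing markers default to 1).
#' @param diets Character vector of diet categories the table must cover.
#' @return An object of class `diet_modifier_table`.
#' @export
diet_modifier_table <- function(modifiers, diets = admito_diets()) {
  stopifnot(is.list(modifiers))
  missing <- setdiff(diets, names(modifiers))
  for (d in missing) modifiers[[d]] <- numeric(0)
  extra <- setdiff(names(modifiers), diets)
  if (length(extra)) {
    stop("modifier table names unknown diet(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  for (d in diets) {
    m <- unlist(modifiers[[d]])
    if (is.null(m)) m <- numeric(0)
    if (length(m) && (anyNA(m) || any(m <= 0))) {
      stop(sprintf("diet '%s': odds modifiers must be > 0", d),
           call. = FALSE)
    }
    bad <- setdiff(names(m), admito_markers())
    if (length(bad)) {
      stop(sprintf("diet '%s' modifies unknown marker(s): %s", d,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    modifiers[d] <- list(m)
  }
  if (length(modifiers[["none"]])) {
    if (any(modifiers[["none"]] != 1)) {
      stop("'none' diet must have all-identity modifiers", call. = FALSE)
    }
  }
  structure(list(modifiers = modifiers[diets], diets = diets),
            class = "diet_modifier_table")
}

#' @rdname diet_modifier_table
#' @export
default_diet_modifiers <- function() {
  diet_modifier_table(list(
    HFO   = c(os = 0.5, mfn2 = 2.0, atp = 2.0),
    HL    = c(fis1 = 2.0, ob = 2.0, mfn2 = 0.5),
    starv = c(mfn1 = 2.0, opa1 = 2.0, atp = 2.0),
    CR    = c(fis1 = 2.0, drp1 = 2.0),
    none  = numeric(0)
  ))
}

#' Identity diet modifiers
#'
#' All diets map to all-identity modifiers, so markers are drawn at their
#' raw Table-1 priors irrespective of diet. Used for frequency-recovery
#' checks.
#'
#' @return A [diet_modifier_table()].
#' @export
identity_diet_modifiers <- function() {
  diet_modifier_table(stats::setNames(
    rep(list(numeric(0)), length(admito_diets())), admito_diets()
  ))
}

#' Bundled default configuration
#'
#' The full model configuration: Table-1 priors, the influence graph, the
#' placeholder diet modifiers, default simulation parameters (n = 1000,
#' seed = 1, ages 30-95, five diets) and the default case-evaluation rule.
#'
#' @return An object of class `ad_config`: a list with fields `priors`,
#'   `network`, `diet_modifiers`, `simulation`, `case_rule`.
#' @export
default_config <- function() {
  structure(
    list(
      priors = default_prior_table(),
      network = default_network_spec(),
      diet_modifiers = default_diet_modifiers(),
      simulation = list(n = 1000L, seed = 1L,
                        age_min = 30L, age_max = 95L,
                        diets = admito_diets()),
      case_rule = default_case_rule()
    ),
    class = "ad_config"
  )
}

# ---- configuration file round trip (JSON schema) ---------------------------

.config_to_list <- function(config) {
  pr <- config$priors
  nw <- config$network
  list(
    priors = list(
      markers = as.list(pr$marker_priors),
      age_brackets = pr$age_brackets,
      default_prior = pr$default_prior,
      age_range = pr$age_range
    ),
    network = list(
      nodes = nw$nodes,
      edges = nw$edges,
      cpt_overrides = lapply(nw$cpt_overrides, function(ov) {
        list(child = ov$child, parents = ov$parents,
             probs = as.list(ov$probs))
      })
    ),
    diet_modifiers = lapply(config$diet_modifiers$modifiers, as.list),
    simulation = config$simulation,
    case_rule = list(
      marker_priority = config$case_rule$marker_priority,
      lifestyle_set = config$case_rule$lifestyle_set,
      no_diet_baseline = config$case_rule$no_diet_baseline
    )
  )
}

# list of row-objects (from JSON) -> data.frame; passes data.frames through
.rows_to_df <- function(x) {
  if (is.data.frame(x)) return(x)
  do.call(rbind, lapply(x, function(r) as.data.frame(r)))
}

.config_from_list <- function(raw) {
  d <- default_config()
  get_or <- function(x, key, fb) if (!is.null(x[[key]])) x[[key]] else fb
  priors <- if (is.null(raw$priors)) d$priors else {
    p <- raw$priors
    ab <- .rows_to_df(get_or(p, "age_brackets", d$priors$age_brackets))
    ab$min <- as.integer(ab$min); ab$max <- as.integer(ab$max)
    prior_table(
      marker_priors = unlist(get_or(p, "markers",
                                    as.list(d$priors$marker_priors))),
      age_brackets = ab,
      default_prior = get_or(p, "default_prior", d$priors$default_prior),
      age_range = as.integer(unlist(get_or(p, "age_range",
                                           d$priors$age_range)))
    )
  }
  network <- if (is.null(raw$network)) d$network else {
    nwr <- raw$network
    edges <- .rows_to_df(get_or(nwr, "edges", d$network$edges))
    ovs <- lapply(get_or(nwr, "cpt_overrides", list()), function(ov) {
      list(child = ov$child, parents = unlist(ov$parents),
           probs = unlist(ov$probs))
    })
    network_spec(nodes = unlist(get_or(nwr, "nodes", d$network$nodes)),
                 edges = edges, cpt_overrides = ovs)
  }
  mods <- if (is.null(raw$diet_modifiers)) d$diet_modifiers else {
    sim_diets <- unlist(get_or(get_or(raw, "simulation", list()), "diets",
                               d$simulation$diets))
    diet_modifier_table(lapply(raw$diet_modifiers, unlist),
                        diets = sim_diets)
  }
  sim <- utils::modifyList(d$simulation, get_or(raw, "simulation", list()))
  sim$n <- as.integer(sim$n); sim$seed <- as.integer(sim$seed)
  sim$diets <- unlist(sim$diets)
  rule <- if (is.null(raw$case_rule)) d$case_rule else {
    cr <- raw$case_rule
    case_rule(
      marker_priority = unlist(get_or(cr, "marker_priority",
                                      d$case_rule$marker_priority)),
      lifestyle_set = unlist(get_or(cr, "lifestyle_set",
                                    d$case_rule$lifestyle_set)),
      no_diet_baseline = get_or(cr, "no_diet_baseline",
                                d$case_rule$no_diet_baseline)
    )
  }
  structure(list(priors = priors, network = network, diet_modifiers = mods,
                 simulation = sim, case_rule = rule),
            class = "ad_config")
}

#' Read or write a model configuration
#'
#' The configuration is one JSON document with optional top-level sections
#' `priors`, `network`, `diet_modifiers`, `simulation` and `case_rule`;
#' missing sections fall back to the bundled defaults ([default_config()]).
#' All tables are validated on load (probabilities in \[0, 1\], acyclic
#' graph, positive odds modifiers).
#'
#' @param path File path.
#' @param config An `ad_config` object (for `write_config`).
#' @return `load_config` returns an `ad_config`; `write_config` returns
#'   `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed config file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  known <- c("priors", "network", "diet_modifiers", "simulation", "case_rule")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  .config_from_list(raw)
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ad_config"))
  jsonlite::write_json(.config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Configuration digest
#'
#' Short deterministic polynomial hash of the serialised configuration,
#' recorded in cohort metadata and run reports so runs can be matched to
#' the exact configuration that produced them. Not cryptographic.
#'
#' @param config An `ad_config`.
#' @return 6-hex-digit string.
#' @export
config_digest <- function(config) {
  s <- jsonlite::toJSON(.config_to_list(config), auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 16777213  # largest prime < 2^24
  sprintf("%06x", h)
}
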