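test_that("bundled prior table carries the published estimates", {
  pt <- default_prior_table()
  expect_equal(pt$marker_priors[["drp1"]], 0.743)
  expect_equal(pt$marker_priors[["opa1"]], 0.614)
  expect_equal(pt$marker_priors[["mfn1"]], 0.278)
  expect_equal(pt$marker_priors[["mfn2"]], 0.336)
  expect_equal(pt$marker_priors[["fis1"]], 0.60)
  expect_equal(pt$marker_priors[["ht"]], 0.20)
  expect_equal(pt$marker_priors[["os"]], 0.275)  # midpoint of 25-30%
  expect_equal(pt$marker_priors[["ob"]], 0.034)
  expect_equal(pt$marker_priors[["dp"]], 0.132)
  expect_equal(pt$marker_priors[["pa"]], 0.177)
  expect_equal(pt$age_brackets$p, c(0.04, 0.15, 0.43, 0.38))
  # markers without a published prior fall back to the uniform default
  expect_equal(marker_prior("atp", pt), 0.5)
  expect_equal(marker_prior("db", pt), 0.5)
})

test_that("prior table construction rejects invalid inputs", {
  expect_error(prior_table(c(ht = 1.2),
                           data.frame(min = 30L, max = 95L, p = 0.1)),
               "\\[0, 1\\]")
  expect_error(prior_table(c(ht = 0.2),
                           data.frame(min = c(30L, 60L),
                                      max = c(64L, 95L),
                                      p = c(0.1, 0.2))),
               "disjointly cover")
  expect_error(prior_table(c(ht = 0.2),
                           data.frame(min = 30L, max = 90L, p = 0.1)),
               "disjointly cover")
})

test_that("age_risk returns the published bracket probabilities", {
  expect_equal(age_risk(63), 0.04)
  expect_equal(age_risk(70), 0.15)
  expect_equal(age_risk(80), 0.43)
  expect_equal(age_risk(90), 0.38)
  expect_error(age_risk(29), "age must be")
  expect_error(age_risk(96), "age must be")
})

test_that("age_risk is total on the configured range", {
  pt <- default_prior_table()
  ps <- vapply(30:95, age_risk, numeric(1), priors = pt)
  expect_length(ps, 66)
  expect_true(all(ps %in% pt$age_brackets$p))
})

test_that("validate_dag orders the bundled graph diet-first, AD-last", {
  spec <- default_network_spec()
  ord <- validate_dag(spec)
  expect_true(bf_is_topo_order(ord, spec$nodes, spec$edges))
  expect_true(match("diet", ord) < min(match(c("opa1", "drp1"), ord)))
  expect_true(match("opa1", ord) < match("fusion", ord))
  expect_true(match("fusion", ord) < match("AD", ord))
  expect_equal(ord[length(ord)], "AD")
})

test_that("validate_dag handles degenerate and cyclic graphs", {
  expect_equal(
    validate_dag(list(nodes = "A",
                      edges = data.frame(parent = character(0),
                                         child = character(0),
                                         sign = character(0)))),
    "A")
  cyc <- data.frame(parent = c("A", "B"), child = c("B", "A"),
                    sign = "promoting")
  expect_error(validate_dag(list(nodes = c("A", "B"), edges = cyc)),
               "cyclic.*A|cyclic.*B")
  expect_error(network_spec(c("A", "B"), cyc), "cyclic")
})

test_that("validate_dag agrees with brute-force reachability on random small graphs", {
  set.seed(101)
  for (i in 1:60) {
    g <- random_small_graph(sample(2:6, 1))
    cyclic_oracle <- bf_has_cycle(g$nodes, g$edges)
    res <- tryCatch(validate_dag(g), error = function(e) e)
    if (cyclic_oracle) {
      expect_s3_class(res, "error")
    } else {
      expect_true(bf_is_topo_order(res, g$nodes, g$edges))
    }
  }
})

test_that("network_spec validates endpoints, signs and cpt overrides", {
  nodes <- c("A", "B", "C")
  e <- data.frame(parent = "A", child = "B", sign = "promoting")
  expect_error(network_spec(nodes, data.frame(parent = "A", child = "Z",
                                              sign = "promoting")),
               "not declared")
  expect_error(network_spec(nodes, data.frame(parent = "A", child = "B",
                                              sign = "up")),
               "sign")
  ov_bad <- list(list(child = "C", parents = c("A", "B"),
                      probs = c("00" = 0.1, "11" = 0.9)))
  expect_error(network_spec(nodes, e, ov_bad), "all 4 parent-state")
  ov_ok <- list(list(child = "C", parents = c("A", "B"),
                     probs = c("00" = 0.1, "01" = 0.4,
                               "10" = 0.6, "11" = 0.9)))
  expect_silent(network_spec(nodes, e, ov_ok))
})

test_that("diet modifier table enforces its invariants", {
  expect_error(diet_modifier_table(list(HFO = c(os = -1))), "> 0")
  expect_error(diet_modifier_table(list(none = c(os = 2))), "identity")
  expect_error(diet_modifier_table(list(keto = c(os = 2))), "unknown diet")
  dm <- default_diet_modifiers()
  expect_length(dm$modifiers[["none"]], 0)
  expect_equal(dm$modifiers[["HFO"]][["os"]], 0.5)
  expect_equal(dm$modifiers[["CR"]][["drp1"]], 2.0)
})

test_that("config round-trips through write_config/load_config", {
  cfg <- default_config()
  cfg$priors$marker_priors[["os"]] <- 0.3
  cfg$simulation$n <- 50L
  cfg$network$cpt_overrides <- list(
    list(child = "os", parents = "atp",
         probs = c("0" = 0.3, "1" = 0.1)))
  cfg$network <- network_spec(cfg$network$nodes, cfg$network$edges,
                              cfg$network$cpt_overrides)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  cfg2 <- load_config(path)
  expect_equal(admito:::.config_to_list(cfg2), admito:::.config_to_list(cfg))
  expect_identical(config_digest(cfg2), config_digest(cfg))
})

test_that("load_config falls back to bundled defaults and rejects bad input", {
  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("{}", empty)
  cfg <- load_config(empty)
  expect_identical(config_digest(cfg), config_digest(default_config()))
  expect_equal(cfg$priors$marker_priors[["drp1"]], 0.743)

  bad_prob <- withr::local_tempfile(fileext = ".json")
  writeLines('{"priors": {"markers": {"ht": 1.2}}}', bad_prob)
  expect_error(load_config(bad_prob), "\\[0, 1\\]")

  bad_key <- withr::local_tempfile(fileext = ".json")
  writeLines('{"piors": {}}', bad_key)
  expect_error(load_config(bad_key), "unknown config key.*piors")

  bad_json <- withr::local_tempfile(fileext = ".json")
  writeLines('{"priors": ', bad_json)
  expect_error(load_config(bad_json), "malformed")

  cyclic <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"network": {"nodes": ["A","B"], "edges": ',
                    '[{"parent":"A","child":"B","sign":"promoting"},',
                    '{"parent":"B","child":"A","sign":"promoting"}]}}'),
             cyclic)
  expect_error(load_config(cyclic), "cyclic")
})

test_that("bundled default config file matches in-code defaults", {
  path <- system.file("extdata", "default_config.json", package = "admito")
  expect_identical(config_digest(load_config(path)),
                   config_digest(default_config()))
})
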