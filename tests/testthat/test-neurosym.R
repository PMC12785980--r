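test_that("the packaged rulebase is structurally valid and ontology-complete", {
  rb <- cxr_rulebase()
  preds <- vapply(rb$predicates, `[[`, character(1), "name")
  expect_setequal(preds, cxr_classes())
  # every rule consequent reachable from the root via is-a edges
  for (r in rb$rules) {
    anc <- ontology_ancestors(rb, r$consequent)
    expect_true(rb$ontology$root %in% anc,
                label = sprintf("%s reaches the ontology root", r$consequent))
  }
  expect_true(all(vapply(rb$rules, function(r) length(r$antecedents) >= 1,
                         logical(1))))
})

test_that("a cyclic ontology or unknown consequent is rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  rb <- yaml::read_yaml(system.file("extdata", "rulebase.yaml",
                                    package = "cxrreason"))
  rb$ontology$is_a <- list(list("A", "B"), list("B", "A"))
  yaml::write_yaml(rb, path)
  expect_error(cxr_rulebase(path), "cycle")
  rb2 <- yaml::read_yaml(system.file("extdata", "rulebase.yaml",
                                     package = "cxrreason"))
  rb2$rules[[1]]$consequent <- "Dragon Pox"
  yaml::write_yaml(rb2, path)
  expect_error(cxr_rulebase(path), "unknown predicate")
})

test_that("cues follow their closed-form definitions", {
  st <- generate_phantom(tiny_spec(seed = 7), labels = rep(0L, 14))
  n <- 64
  # synthetic aligned maps: uniform 0.3 over basal lung for the effusion map,
  # constant (zero-gradient) apical map for pneumothorax
  regions <- anatomy_regions(st$lung_mask, st$heart_mask, st$thorax_mask)
  mk <- function(map) {
    structure(list(aligned_map = map, regions = regions), class = "cxr_aligned_saliency")
  }
  aligned <- list(
    Effusion = mk(0.3 * regions$basal_lung),
    Pneumothorax = mk(matrix(0, n, n))
  )
  cues <- compute_cues(aligned, st$lung_mask, st$heart_mask, st$thorax_mask,
                       image = st$image)
  v <- setNames(cues$value, cues$cue)
  expect_equal(unname(v["cardiothoracic_ratio"]),
               sum(st$heart_mask) / sum(st$thorax_mask), tolerance = 1e-12)
  expect_equal(unname(v["basal_activation"]), 0.3, tolerance = 1e-12)
  expect_equal(unname(v["apical_gradient"]), 0) # phi(0) = 0 by construction
  # hand pixel-count division on a toy pair of masks
  heart <- matrix(0, 10, 10)
  heart[1:5, 1:5] <- 1 # 25 px
  thorax <- matrix(1, 10, 10) # 100 px
  lung <- matrix(0, 10, 10)
  lung[6:10, ] <- 1
  cues2 <- compute_cues(list(), lung, heart, thorax)
  expect_equal(cues2$value[cues2$cue == "cardiothoracic_ratio"], 0.25)
  expect_error(compute_cues(list(), lung, heart, matrix(0, 10, 10)), "empty")
})

test_that("fuzzy membership is a centred, saturating, increasing logistic", {
  expect_equal(fuzzy_membership(0.4, 10, 0.4), 0.5)
  expect_equal(fuzzy_membership(0.4 + log(3) / 10, 10, 0.4), 0.75,
               tolerance = 1e-12)
  expect_equal(fuzzy_membership(0.6, 1e3, 0.4), 1, tolerance = 1e-6)
  expect_equal(fuzzy_membership(0.2, 1e3, 0.4), 0, tolerance = 1e-6)
  grid <- seq(0, 1, by = 0.05)
  mu <- fuzzy_membership(grid, 7, 0.3)
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu > 0 & mu < 1))
  expect_error(fuzzy_membership(0.5, beta = -1))
})

test_that("rules fire on strict comparisons and match a loop interpreter", {
  values <- c(mu_e = 0.9, a_costo = 0.8, mu_p = 0.5)
  rules <- list(
    list(id = "r1", antecedents = list(list(cue = "mu_e", op = ">", threshold = 0.5),
                                       list(cue = "a_costo", op = ">", threshold = 0.5)),
         consequent = "Effusion", confidence = "mu_e"),
    list(id = "r2", antecedents = list(list(cue = "mu_p", op = ">", threshold = 0.5)),
         consequent = "Pneumothorax", confidence = "mu_p")
  )
  fired <- evaluate_rules(values, rules)
  expect_equal(fired$predicate, "Effusion")
  expect_equal(fired$confidence, 0.9)
  # boundary: exactly at the threshold does NOT fire (strict >)
  expect_false("Pneumothorax" %in% fired$predicate)
  expect_error(
    evaluate_rules(values, list(list(id = "bad",
                                     antecedents = list(list(cue = "ghost", threshold = 0)),
                                     consequent = "X", confidence = "mu_e"))),
    "unknown cue"
  )
})

test_that("random rulebases agree with the interpreter oracle", {
  set.seed(21)
  for (rep in 1:10) {
    cues <- setNames(runif(6), paste0("c", 1:6))
    rules <- lapply(1:5, function(i) {
      k <- sample(1:3, 1)
      list(
        id = paste0("r", i),
        antecedents = lapply(sample(names(cues), k), function(cn) {
          list(cue = cn, op = sample(c(">", "<"), 1), threshold = runif(1))
        }),
        consequent = paste0("D", i),
        confidence = sample(names(cues), 1)
      )
    })
    got <- evaluate_rules(cues, rules)
    ref <- rule_interpreter_oracle(as.list(cues), rules)
    expect_equal(got$rule_id, vapply(ref, `[[`, character(1), "id"))
    expect_equal(got$confidence, vapply(ref, `[[`, numeric(1), "confidence"))
  }
})

test_that("belief aggregation is the weighted mean with conflict attenuation", {
  b <- tibble::tibble(predicate = c("A", "A"), mu = c(0.2, 0.8), weight = 1)
  expect_equal(resolve_conflicts(b)$mu_final, 0.5)
  b1 <- tibble::tibble(predicate = "B", mu = 0.7, weight = 2)
  expect_equal(resolve_conflicts(b1)$mu_final, 0.7)
  b2 <- tibble::tibble(predicate = c("C", "C"), mu = c(0.2, 0.6),
                       weight = c(1, 3))
  expect_equal(resolve_conflicts(b2)$mu_final, 0.5)
  # uniform weight rescaling leaves the result unchanged
  b3 <- b2
  b3$weight <- b3$weight * 17
  expect_equal(resolve_conflicts(b3)$mu_final, 0.5)
  expect_error(resolve_conflicts(tibble::tibble(predicate = "D", mu = 0.5,
                                                weight = 0)), "zero")
  # conflicting pair both supported: the lower member is halved
  b4 <- tibble::tibble(predicate = c("Pneumothorax", "Effusion"),
                       mu = c(0.9, 0.7), weight = 1)
  out <- resolve_conflicts(b4, list(list(a = "Pneumothorax", b = "Effusion")))
  expect_equal(out$mu_final[out$predicate == "Effusion"], 0.35)
  expect_true(out$attenuated[out$predicate == "Effusion"])
  expect_equal(out$mu_final[out$predicate == "Pneumothorax"], 0.9)
})

test_that("hypothesis ranking is a sharpened softmax with stable ties", {
  r <- rank_hypotheses(c(A = 1, B = 1, C = 1), alpha = 3)
  expect_equal(r$probability, rep(1 / 3, 3))
  expect_equal(r$predicate, c("A", "B", "C")) # name order on ties
  r2 <- rank_hypotheses(c(A = 9, B = -4), alpha = 0)
  expect_equal(r2$probability, c(0.5, 0.5))
  r3 <- rank_hypotheses(c(x = 1, y = 0), alpha = 1)
  expect_equal(r3$probability, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-10)
  expect_equal(r3$probability[1], 0.7311, tolerance = 1e-4)
  expect_equal(sum(r3$probability), 1, tolerance = 1e-12)
  # order isomorphic to scores for alpha > 0
  set.seed(22)
  s <- setNames(runif(8), paste0("h", 1:8))
  r4 <- rank_hypotheses(s, alpha = 5)
  expect_equal(r4$predicate, names(sort(s, decreasing = TRUE)))
  expect_error(rank_hypotheses(numeric(0)), "empty")
})

test_that("reports carry the four required fields, templates and ordering", {
  rb <- cxr_rulebase()
  fired <- tibble::tibble(rule_id = c("effusion_costophrenic", "edema_region"),
                          predicate = c("Effusion", "Edema"),
                          confidence = c(0.9, 0.6))
  ranked <- rank_hypotheses(setNames(fired$confidence, fired$predicate),
                            alpha = 5)
  rep <- generate_report(ranked, fired, rb,
                         metadata = list(study_index = 7L),
                         energies = c(Effusion = 0.4, Edema = 0.2))
  expect_s3_class(rep, "cxr_report")
  expect_length(rep$findings, 2L)
  f1 <- rep$findings[[1]]
  expect_named(f1, c("disease_label", "probability", "region", "text",
                     "rule_id", "region_energy"), ignore.order = TRUE)
  expect_equal(f1$disease_label, "Effusion")
  expect_match(f1$text, "compatible with pleural effusion")
  expect_match(f1$text, "marked") # mu 0.9 maps to the strongest band
  expect_equal(f1$rule_id, "effusion_costophrenic")
  # findings sorted by probability descending (sort oracle)
  probs <- vapply(rep$findings, `[[`, numeric(1), "probability")
  expect_equal(probs, sort(probs, decreasing = TRUE))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  # empty hypothesis set still yields a valid report
  empty <- generate_report(
    tibble::tibble(predicate = character(), score = numeric(),
                   probability = numeric(), rank = integer()),
    fired[0, ], rb
  )
  expect_length(empty$findings, 0L)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed$findings, 2L)
  expect_equal(parsed$findings[[1]]$disease_label, "Effusion")
  # missing template errors
  rb2 <- rb
  rb2$predicates <- purrr::map(rb2$predicates, function(p) {
    if (p$name == "Effusion") p$template <- NULL
    p
  })
  expect_error(generate_report(ranked, fired, rb2), "template")
})
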