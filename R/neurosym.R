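# Ontology-grounded fuzzy reasoning: continuous anatomical cues are mapped to
# fuzzy predicate memberships, aggregated and conflict-resolved, passed
# through Horn-clause rules, ranked by a sharpened softmax, and rendered as a
# templated, machine-readable diagnostic report.

#' Load the rulebase and ontology
#'
#' Reads the YAML rulebase (predicates with region bindings and fuzzy
#' reference levels, is-a ontology edges, Horn-clause rules, conflict pairs,
#' report templates, and the fuzzy/ranking constants). The packaged default
#' encodes the two explicit clauses for effusion and pneumothorax, a
#' cardiothoracic-ratio clause for cardiomegaly, and one templated clause per
#' remaining class bound to its primary anatomical region; it is a documented
#' reconstruction and fully editable.
#'
#' @param path Optional path to a rulebase YAML; defaults to the packaged
#'   one.
#' @return A list of class `cxr_rulebase`.
#' @export
cxr_rulebase <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rulebase.yaml", package = "cxrreason")
  }
  rb <- yaml::read_yaml(path)
  # validate: acyclic is-a graph, known consequents, antecedents present
  preds <- vapply(rb$predicates, `[[`, character(1), "name")
  for (r in rb$rules) {
    if (!r$consequent %in% preds) {
      abort(sprintf("rule '%s' names unknown predicate '%s'", r$id, r$consequent))
    }
    if (length(r$antecedents) < 1L) abort("rules need at least one antecedent")
  }
  edges <- rb$ontology$is_a
  if (length(edges)) {
    parent_of <- setNames(
      vapply(edges, function(e) e[[2]], character(1)),
      vapply(edges, function(e) e[[1]], character(1))
    )
    for (start in names(parent_of)) {
      seen <- character()
      cur <- start
      while (cur %in% names(parent_of)) {
        if (cur %in% seen) abort("is-a graph contains a cycle")
        seen <- c(seen, cur)
        cur <- parent_of[[cur]]
      }
    }
  }
  structure(rb, class = c("cxr_rulebase", "list"))
}

#' Ancestors of a predicate in the ontology
#'
#' @param rulebase A `cxr_rulebase`.
#' @param predicate Predicate name.
#' @return Character vector of ancestors (nearest first).
#' @export
ontology_ancestors <- function(rulebase, predicate) {
  edges <- rulebase$ontology$is_a
  parent_of <- setNames(
    vapply(edges, function(e) e[[2]], character(1)),
    vapply(edges, function(e) e[[1]], character(1))
  )
  out <- character()
  cur <- predicate
  while (cur %in% names(parent_of)) {
    cur <- parent_of[[cur]]
    out <- c(out, cur)
  }
  out
}

#' Continuous confidence cues from aligned saliency and masks
#'
#' Computes the per-study cue record: the cardiothoracic area ratio
#' `A_heart / A_thorax`; the effusion cue (mean normalized aligned activation
#' of the effusion map over the basal lung); the pneumothorax cue
#' `phi(grad L_apex)` where the gradient is the mean finite-difference
#' magnitude of the pneumothorax map over the apical region and
#' `phi(g) = min(1, g / g95)` with `g95` the 95th percentile of gradient
#' magnitude over the whole lung (`phi(0) = 0`); a per-class activation cue
#' (mean normalized aligned activation of that class's map over its bound
#' region); and the basal image density (mean basal pixel intensity / 255).
#'
#' @param aligned Named list of `cxr_aligned_saliency`, one per class name.
#' @param lung_mask,heart_mask,thorax_mask Binary masks.
#' @param image Optional gray image in `[0, 255]` for the density cue.
#' @param bindings Optional named vector mapping class names to region names
#'   (from the rulebase); classes default to the whole lung.
#' @return A tibble with columns `cue`, `value`.
#' @export
compute_cues <- function(aligned, lung_mask, heart_mask, thorax_mask,
                         image = NULL, bindings = NULL) {
  if (sum(thorax_mask) == 0) abort("thorax mask is empty")
  regions <- anatomy_regions(lung_mask, heart_mask, thorax_mask)
  cues <- list(cardiothoracic_ratio = sum(heart_mask) / sum(thorax_mask))
  grad_mag <- function(m) {
    gy <- rbind(diff(m), 0)
    gx <- cbind(t(diff(t(m))), 0)
    sqrt(gy^2 + gx^2)
  }
  for (nm in names(aligned)) {
    amap <- aligned[[nm]]$aligned_map
    key <- gsub(" ", "_", tolower(nm))
    if (nm == "Effusion") {
      cues[["basal_activation"]] <- region_energy(amap, regions$basal_lung)
    }
    if (nm == "Pneumothorax") {
      g <- grad_mag(amap)
      gl <- g[regions$lung == 1]
      g95 <- if (length(gl)) as.numeric(quantile(gl, 0.95)) else 0
      ga <- region_energy(g, regions$apical_lung)
      cues[["apical_gradient"]] <- if (g95 > 0) min(1, ga / g95) else 0
    }
    reg_name <- bindings[[nm]] %||% "lung"
    reg <- regions[[reg_name]] %||% regions$lung
    if (sum(reg) == 0) reg <- regions$lung
    cues[[paste0("activation_", key)]] <- region_energy(amap, reg)
  }
  if (!is.null(image)) {
    cues[["basal_image_density"]] <-
      sum(image * regions$basal_lung) / (255 * max(1, sum(regions$basal_lung)))
  }
  tibble::tibble(cue = names(cues), value = as.numeric(unlist(cues)))
}

#' Fuzzy membership of a confidence cue
#'
#' Logistic transform `1 / (1 + exp(-beta (conf - tau)))`: 0.5 exactly at
#' the reference level, saturating with sharpness `beta`.
#'
#' @param conf Numeric confidence value(s).
#' @param beta Sharpness (> 0).
#' @param tau Reference level.
#' @return Membership value(s) in `(0, 1)`.
#' @export
fuzzy_membership <- function(conf, beta = 10, tau = 0.5) {
  stopifnot(beta > 0)
  logistic(beta * (conf - tau))
}

#' Evaluate Horn-clause rules against named values
#'
#' A rule fires iff every antecedent comparison holds strictly
#' (`value > threshold`, or `<` when `op = "<"`). The fired consequent
#' carries the membership named by the rule's `confidence` field. Multiple
#' rules may fire (multi-label).
#'
#' @param values Named numeric vector of cue values, memberships and region
#'   energies.
#' @param rules List of rules: each `list(id, antecedents = list(list(cue,
#'   op, threshold)), consequent, confidence)`.
#' @return Tibble with `rule_id`, `predicate`, `confidence` for fired rules.
#' @export
evaluate_rules <- function(values, rules) {
  fired <- purrr::map_dfr(rules, function(r) {
    ok <- TRUE
    for (a in r$antecedents) {
      if (!a$cue %in% names(values)) {
        abort(sprintf("rule '%s' references unknown cue '%s'", r$id, a$cue))
      }
      v <- values[[a$cue]]
      op <- a$op %||% ">"
      hit <- if (op == ">") v > a$threshold else v < a$threshold
      if (!isTRUE(hit)) {
        ok <- FALSE
        break
      }
    }
    if (!ok) {
      return(NULL)
    }
    conf_key <- r$confidence
    if (!conf_key %in% names(values)) {
      abort(sprintf("rule '%s' confidence source '%s' missing", r$id, conf_key))
    }
    tibble::tibble(rule_id = r$id, predicate = r$consequent,
                   confidence = values[[conf_key]])
  })
  if (nrow(fired) == 0L) {
    fired <- tibble::tibble(rule_id = character(), predicate = character(),
                            confidence = numeric())
  }
  fired
}

#' Aggregate per-cue memberships and resolve conflicts
#'
#' Per predicate, `mu_final = sum(w_k mu_k) / sum(w_k)`. For each declared
#' conflicting pair with both members supported above their reference level,
#' the lower-`mu_final` member is attenuated by the penalty factor.
#'
#' @param beliefs Tibble with columns `predicate`, `mu`, `weight` (one row
#'   per cue contribution).
#' @param conflict_pairs List of `list(a, b)` predicate-name pairs (region
#'   qualifiers may be carried as extra fields; attenuation applies when both
#'   are supported).
#' @param tau_ref Named vector of per-predicate reference levels (default
#'   0.5).
#' @param penalty Multiplicative attenuation for the losing member.
#' @return Tibble of class `cxr_beliefs`: `predicate`, `mu_final`,
#'   `attenuated`.
#' @export
resolve_conflicts <- function(beliefs, conflict_pairs = list(), tau_ref = NULL,
                              penalty = 0.5) {
  stopifnot(all(c("predicate", "mu") %in% names(beliefs)))
  if (!"weight" %in% names(beliefs)) beliefs$weight <- 1
  if (any(beliefs$weight < 0)) abort("weights must be non-negative")
  out <- beliefs %>%
    dplyr::group_by(.data$predicate) %>%
    dplyr::summarise(
      wsum = sum(.data$weight),
      mu_final = if (sum(.data$weight) == 0) {
        abort("all-zero weights for a predicate")
      } else {
        sum(.data$weight * .data$mu) / sum(.data$weight)
      },
      .groups = "drop"
    ) %>%
    dplyr::select("predicate", "mu_final") %>%
    dplyr::mutate(attenuated = FALSE)
  ref <- function(p) {
    if (!is.null(tau_ref) && p %in% names(tau_ref)) tau_ref[[p]] else 0.5
  }
  for (cp in conflict_pairs) {
    a <- cp$a %||% cp[[1]]
    b <- cp$b %||% cp[[2]]
    ia <- match(a, out$predicate)
    ib <- match(b, out$predicate)
    if (is.na(ia) || is.na(ib)) next
    if (out$mu_final[ia] > ref(a) && out$mu_final[ib] > ref(b)) {
      lose <- if (out$mu_final[ia] <= out$mu_final[ib]) ia else ib
      out$mu_final[lose] <- out$mu_final[lose] * penalty
      out$attenuated[lose] <- TRUE
    }
  }
  class(out) <- c("cxr_beliefs", class(out))
  out
}

#' Rank hypotheses with a sharpened softmax
#'
#' `P(D_i) = exp(alpha S_i) / sum_j exp(alpha S_j)`; `alpha = 0` gives a
#' uniform distribution. Ordering is descending in probability with stable
#' ties by predicate name.
#'
#' @param scores Named numeric vector of condition scores `S_i`.
#' @param alpha Ranking sharpness (>= 0).
#' @return Tibble `predicate`, `score`, `probability`, `rank`.
#' @export
rank_hypotheses <- function(scores, alpha = 5) {
  if (length(scores) == 0L) abort("empty hypothesis set")
  s <- alpha * scores
  s <- s - max(s)
  p <- exp(s) / sum(exp(s))
  ord <- order(-p, names(scores))
  tibble::tibble(
    predicate = names(scores)[ord], score = as.numeric(scores)[ord],
    probability = as.numeric(p)[ord], rank = seq_along(scores)
  )
}

# qualitative strength band used in templated sentences
strength_band <- function(mu) {
  if (mu > 0.8) "marked" else if (mu >= 0.6) "likely" else "mild"
}

#' Assemble the structured diagnostic report
#'
#' One finding per ranked hypothesis, each carrying the disease label, its
#' ranking probability, the bound body region, a templated sentence (with
#' region and qualitative strength band filled in), and traceability fields
#' naming the fired rule and its region energy.
#'
#' @param ranked Tibble from [rank_hypotheses()].
#' @param fired Tibble from [evaluate_rules()] (provides rule ids).
#' @param rulebase A `cxr_rulebase` (templates and region bindings).
#' @param metadata Named list merged into the report header.
#' @param energies Optional named vector of region energies per predicate.
#' @return A list of class `cxr_report`.
#' @export
generate_report <- function(ranked, fired, rulebase, metadata = list(),
                            energies = NULL) {
  preds <- purrr::set_names(
    rulebase$predicates,
    vapply(rulebase$predicates, `[[`, character(1), "name")
  )
  findings <- purrr::map(seq_len(nrow(ranked)), function(i) {
    nm <- ranked$predicate[i]
    pr <- preds[[nm]]
    if (is.null(pr) || is.null(pr$template)) {
      abort(sprintf("missing template for predicate '%s'", nm))
    }
    region <- pr$region %||% "thorax"
    txt <- gsub("{region}", gsub("_", " ", region), pr$template, fixed = TRUE)
    txt <- gsub("{strength}", strength_band(ranked$score[i]), txt, fixed = TRUE)
    rid <- fired$rule_id[match(nm, fired$predicate)]
    list(
      disease_label = nm,
      probability = ranked$probability[i],
      region = region,
      text = txt,
      rule_id = if (is.na(rid)) NULL else rid,
      region_energy = if (!is.null(energies) && nm %in% names(energies)) {
        as.numeric(energies[[nm]])
      } else {
        NULL
      }
    )
  })
  structure(
    c(list(findings = findings), metadata),
    class = "cxr_report"
  )
}

#' Serialize a report to JSON
#'
#' @param report A `cxr_report`.
#' @param path Output path.
#' @return `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}
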