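#' Run the full analysis pipeline on a simulated study
#'
#' Composes the stages — simulation, rate maps and classification, cross-
#' session stability, lap-to-lap reliability, manifold embedding and position
#' decoding — under a single seed, so the same configuration and seed
#' reproduce identical results. Stages can be switched off; later stages that
#' depend on a disabled one are skipped.
#'
#' @param config A [sim_config()].
#' @param n_sessions,environments Passed to [simulate_study()].
#' @param stages Character subset of `c("classify", "stability",
#'   "reliability", "manifold", "decode")`.
#' @param n_shuffles Shuffle count for the chance criterion.
#' @param seed Integer seed (defaults to the configuration's).
#' @param manifold_max_frames Frame cap for the embedding stage.
#' @param decode_dims Number of manifold components used by the decoder.
#' @return Object of class `pipeline_results`: per-session `classification`,
#'   `stability` (pairwise), `reliability` (per-cell exponents), `manifold`,
#'   `decoding`, a `summary` data frame (including classification sensitivity
#'   and false-positive rate against the simulation ground truth), and a
#'   `seed_manifest` recording the seed of every stage.
#' @export
run_pipeline <- function(config,
                         n_sessions = 1,
                         environments = "A",
                         stages = c("classify", "stability", "reliability",
                                    "manifold", "decode"),
                         n_shuffles = 1000,
                         seed = config$rng_seed,
                         manifold_max_frames = 1000,
                         decode_dims = 3) {
  stages <- match.arg(stages, several.ok = TRUE)
  study <- simulate_study(config, n_sessions, environments, seed = seed)
  manifest <- list(top = seed,
                   shuffle = derive_seed(seed, 900L),
                   decode = derive_seed(seed, 901L))
  out <- list(config = config, study = study, seed_manifest = manifest,
              classification = NULL, stability = NULL, reliability = NULL,
              manifold = NULL, decoding = NULL, summary = NULL)

  if ("classify" %in% stages) {
    out$classification <- lapply(study, function(se)
      classify_cells(se$session, n_shuffles = n_shuffles,
                     seed = manifest$shuffle))
    out$summary <- do.call(rbind, lapply(seq_along(study), function(s) {
      truth <- study[[s]]$truth
      tab <- out$classification[[s]]$table
      part <- if (!is.null(truth$participating)) truth$participating
              else rep(TRUE, nrow(truth))
      tuned <- truth$type == "place" & part
      untuned <- truth$type != "place" & part
      data.frame(
        session = s,
        environment = study[[s]]$session$environment,
        day = study[[s]]$session$day,
        n_cells = nrow(tab),
        n_place_cells = sum(tab$is_place_cell),
        sensitivity = if (any(tuned))
          mean(tab$is_place_cell[tuned]) else NA_real_,
        false_positive_rate = if (any(untuned))
          mean(tab$is_place_cell[untuned]) else NA_real_,
        running_fraction = study[[s]]$session$running_fraction)
    }))
  }

  if ("stability" %in% stages && !is.null(out$classification) &&
      n_sessions > 1) {
    pairs <- utils::combn(n_sessions, 2, simplify = FALSE)
    out$stability <- lapply(pairs, function(pr) {
      st <- session_pair_stats(out$classification[[pr[1]]],
                               out$classification[[pr[2]]])
      st$sessions <- pr
      st
    })
  }

  if ("reliability" %in% stages && config$arena == "circular_track") {
    out$reliability <- lapply(study, function(se)
      reliability_exponents(se$session))
  }

  if ("manifold" %in% stages) {
    out$manifold <- lapply(study, function(se) {
      pop <- population_matrix(se$session, max_frames = manifold_max_frames)
      embed_population(pop)
    })
    if ("decode" %in% stages) {
      out$decoding <- lapply(out$manifold, function(emb) {
        nd <- min(decode_dims, nrow(emb$Y))
        decode_position_cv(emb, n_dims = nd, seed = manifest$decode)
      })
    }
  }
  class(out) <- "pipeline_results"
  out
}

#' @export
print.pipeline_results <- function(x, ...) {
  cat("<pipeline_results>", length(x$study), "session(s)\n")
  if (!is.null(x$summary)) {
    cat("  classification summary:\n")
    print(x$summary, row.names = FALSE)
  }
  if (!is.null(x$decoding))
    cat("  decoding r:",
        paste(sprintf("%.3f", vapply(x$decoding, `[[`, 0, "r")),
              collapse = ", "), "\n")
  invisible(x)
}
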