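#' Greedy network-constrained selection of dysregulated pathways
#'
#' Forward feature selection over pathway activities, constrained by the
#' pathway interaction network. The first marker is the single pathway whose
#' activity best discriminates disease from control by repeated
#' cross-validated SVM AUC; each subsequent step evaluates every unselected
#' PIN neighbor of the growing marker set appended to it, accepting the best
#' candidate only if it improves the mean AUC by more than
#' `cfg$improvement_tol`. The search stops when no candidate improves or the
#' neighbor pool is empty; the accepted set is then re-scored at the full
#' repeat count.
#'
#' Ties at any step are broken by the lexicographically smallest pathway id.
#' Candidates within one step share identical fold partitions (see
#' [eval_config()]'s seed policy), so their AUCs are paired comparisons.
#'
#' @param activity A `pathway_activity` object covering the PIN's nodes.
#' @param pin A `pathway_pin` object.
#' @param labels Labels tibble (`sample`, `label`).
#' @param cfg An [eval_config()].
#' @return A `pathway_selection` object with `$steps` (trace tibble: step,
#'   pathway, pool_size, mean_auc, auc_sd), `$final_set`, `$final_auc`,
#'   `$final_auc_sd`, `$step1_scan` (the full single-pathway scan), `$cfg`.
#' @export
greedy_select <- function(activity, pin, labels, cfg = eval_config()) {
  stopifnot(inherits(pin, "pathway_pin"))
  scores <- if (inherits(activity, "pathway_activity")) {
    activity$scores
  } else {
    activity
  }
  nodes <- intersect(pin$nodes, scores$pathway)
  if (length(nodes) == 0L) {
    abort("pathway interaction network is empty or disjoint from activity")
  }
  nodes <- sort(nodes)

  screen <- function(feature_sets) {
    purrr::map_dfr(feature_sets, function(fs) {
      evaluate_feature_set(scores, labels, fs, cfg,
                           n_repeats = cfg$search_repeats)
    })
  }

  # Step 1: exhaustive single-pathway scan.
  scan <- screen(as.list(nodes)) |>
    dplyr::mutate(pathway = nodes, .before = 1L)
  best <- scan |>
    dplyr::arrange(dplyr::desc(.data$mean_auc), .data$pathway) |>
    dplyr::slice(1L)
  selected <- best$pathway
  current_auc <- best$mean_auc
  steps <- tibble::tibble(
    step = 1L, pathway = best$pathway, pool_size = length(nodes),
    mean_auc = best$mean_auc, auc_sd = best$auc_sd
  )

  repeat {
    anchor <- if (cfg$frontier == "first-only") selected[1L] else selected
    pool <- pin_neighbors(pin, anchor)
    pool <- sort(setdiff(intersect(pool, nodes), selected))
    if (length(pool) == 0L) break
    cand <- screen(purrr::map(pool, ~ c(selected, .x))) |>
      dplyr::mutate(pathway = pool, .before = 1L) |>
      dplyr::arrange(dplyr::desc(.data$mean_auc), .data$pathway)
    best <- dplyr::slice(cand, 1L)
    if (best$mean_auc <= current_auc + cfg$improvement_tol) break
    selected <- c(selected, best$pathway)
    current_auc <- best$mean_auc
    steps <- dplyr::bind_rows(steps, tibble::tibble(
      step = nrow(steps) + 1L, pathway = best$pathway,
      pool_size = length(pool),
      mean_auc = best$mean_auc, auc_sd = best$auc_sd
    ))
  }

  final <- evaluate_feature_set(scores, labels, selected, cfg,
                                n_repeats = cfg$n_repeats)
  structure(
    list(
      steps = steps,
      final_set = selected,
      final_auc = final$mean_auc,
      final_auc_sd = final$auc_sd,
      step1_scan = scan,
      cfg = cfg
    ),
    class = "pathway_selection"
  )
}

#' @export
print.pathway_selection <- function(x, ...) {
  cat("<pathway_selection> ", length(x$final_set), " marker(s), final CV-AUC ",
      sprintf("%.3f", x$final_auc), " (", x$cfg$n_repeats, " repeats)\n",
      sep = "")
  print(x$steps)
  invisible(x)
}

#' @describeIn greedy_select Selection trace, one row per accepted step.
#' @param x A `pathway_selection` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pathway_selection <- function(x, ...) {
  x$steps
}

#' @describeIn greedy_select One-row summary of the final marker set.
#' @exportS3Method generics::glance
glance.pathway_selection <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$final_set),
    final_auc = x$final_auc,
    final_auc_sd = x$final_auc_sd,
    n_folds = x$cfg$n_folds,
    n_repeats = x$cfg$n_repeats,
    seed = x$cfg$seed
  )
}

#' Plot the greedy selection trace
#'
#' Mean cross-validated AUC (with one-standard-deviation ribbon over CV
#' repeats) against the accepted selection steps.
#'
#' @param object A `pathway_selection` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pathway_selection <- function(object, ...) {
  df <- object$steps
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$mean_auc)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_auc - .data$auc_sd,
                   ymax = pmin(1, .data$mean_auc + .data$auc_sd)),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$pathway),
                       vjust = 1.8, size = 3) +
    ggplot2::scale_x_continuous(breaks = df$step) +
    ggplot2::labs(x = "selection step", y = "mean CV-AUC") +
    ggplot2::theme_bw()
}

#' Write the selection trace and final marker list
#'
#' @param selection A `pathway_selection` object.
#' @param trace_path Output TSV for the per-step trace.
#' @param markers_path Optional output TSV for the final marker list.
#' @return The selection, invisibly.
#' @export
write_selection <- function(selection, trace_path, markers_path = NULL) {
  readr::write_tsv(selection$steps, trace_path, progress = FALSE)
  if (!is.null(markers_path)) {
    readr::write_tsv(
      tibble::tibble(rank = seq_along(selection$final_set),
                     pathway = selection$final_set),
      markers_path, progress = FALSE
    )
  }
  invisible(selection)
}
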