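#' Default lineage marker panel
#'
#' Master regulator plus signature cytokine per lineage (FOXP3 alone for
#' iTreg), matching how phenotype is read off dominant markers in flow
#' cytometry panels.
#' @return Named list: lineage -> character vector of marker species ids.
#' @export
lineage_markers <- function() {
  list(
    Th1 = c("Tbet", "IFNg_s"),
    Th2 = c("GATA3", "IL4_s"),
    Th17 = c("RORgt", "IL17_s"),
    iTreg = "FOXP3"
  )
}

#' Reference marker levels under canonical induction
#'
#' Each marker is normalized by its own level at the endpoint of its
#' lineage's canonical induction, putting markers with different dynamic
#' ranges on a comparable scale. Results are memoized per model.
#'
#' @param model A `cd4_model` (for perturbed models pass the wild-type model
#'   whose scale should define "fully induced").
#' @param markers Marker panel as in [lineage_markers()].
#' @param t_end Induction horizon in hours.
#' @return Named list: lineage -> named vector of reference levels (a.u.).
#' @export
classifier_reference <- function(model, markers = lineage_markers(),
                                 t_end = 100) {
  key <- rlang::hash(list(model$parameters, model$species, markers, t_end,
                          model$metadata$clamps,
                          model$metadata$disabled_reactions))
  cached <- .cd4_cache[[key]]
  if (!is.null(cached)) return(cached)
  refs <- lapply(names(markers), function(lin) {
    ep <- endpoint_state(simulate_time_course(model, canonical_recipe(lin),
                                              t_end = t_end, n_points = 200))
    ep[markers[[lin]]]
  })
  names(refs) <- names(markers)
  .cd4_cache[[key]] <- refs
  refs
}

.cd4_cache <- new.env(parent = emptyenv())

#' Classify a state into a CD4+ T cell phenotype
#'
#' Lineage scores are geometric means of each lineage's markers normalized by
#' their reference (canonically induced) levels. The call is the argmax
#' lineage provided it dominates: the top score must be at least
#' `thresholds$ratio` times the runner-up and above `thresholds$floor`
#' (fraction of full induction); otherwise the call is `naive_mixed`.
#' Reported scores are normalized to sum to one.
#'
#' @param state Named vector of species levels containing every marker.
#' @param reference Reference levels from [classifier_reference()].
#' @param markers Marker panel (see [lineage_markers()]).
#' @param thresholds List with `ratio` (dominance ratio, default 2) and
#'   `floor` (minimum top score, default 0.05).
#' @return A `cd4_phenotype_call`: `label`, normalized `scores`, raw
#'   `raw_scores`, and the panel used.
#' @export
classify_phenotype <- function(state, reference,
                               markers = lineage_markers(),
                               thresholds = list(ratio = 2, floor = 0.05)) {
  all_markers <- unique(unlist(markers))
  missing_m <- setdiff(all_markers, names(state))
  if (length(missing_m)) {
    stop("state is missing marker species: ", paste(missing_m, collapse = ", "))
  }
  raw <- vapply(names(markers), function(lin) {
    m <- markers[[lin]]
    ref <- reference[[lin]][m]
    if (any(!is.finite(ref)) || any(ref <= 0)) {
      stop("non-positive reference level for lineage ", lin)
    }
    norm <- pmax(state[m], 0) / ref
    if (any(norm == 0)) 0 else exp(mean(log(norm)))
  }, numeric(1))
  ord <- order(raw, decreasing = TRUE)
  top <- raw[ord[1]]
  runner <- if (length(raw) > 1L) raw[ord[2]] else 0
  label <- if (top < thresholds$floor || top < thresholds$ratio * runner) {
    "naive_mixed"
  } else {
    names(raw)[ord[1]]
  }
  scores <- if (sum(raw) > 0) raw / sum(raw) else
    stats::setNames(rep(1 / length(raw), length(raw)), names(raw))
  structure(list(label = label, scores = scores, raw_scores = raw,
                 markers = markers, thresholds = thresholds),
            class = "cd4_phenotype_call")
}

#' @export
print.cd4_phenotype_call <- function(x, ...) {
  cat("<phenotype call> ", x$label, " (scores: ",
      paste0(names(x$scores), "=", signif(x$scores, 3), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
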