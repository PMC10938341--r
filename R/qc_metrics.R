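#' Mesh topology summary
#'
#' Counts vertices, unique undirected edges and faces of a triangle
#' mesh and derives the Euler characteristic `chi = V - E + F` and the
#' defect index `(2 - chi) / 2` — the number of topological handles of
#' a closed connected orientable surface, the automated proxy for
#' reconstruction quality (a perfect cortical hemisphere is a
#' topological sphere, chi = 2, zero defects).
#'
#' @param mesh A [tri_mesh].
#' @return List with `n_vertices`, `n_edges`, `n_faces`, `euler`,
#'   `defect_index`, `n_components` (edge-connectivity components).
#' @export
mesh_topology <- function(mesh) {
  v <- nrow(mesh$vertices)
  f <- nrow(mesh$faces)
  fc <- mesh$faces
  e_all <- rbind(fc[, c(1, 2)], fc[, c(2, 3)], fc[, c(3, 1)])
  e_can <- cbind(pmin(e_all[, 1], e_all[, 2]),
                 pmax(e_all[, 1], e_all[, 2]))
  key <- (as.numeric(e_can[, 1]) - 1) * v + as.numeric(e_can[, 2])
  e <- length(unique(key))
  g <- igraph::graph_from_edgelist(e_can, directed = FALSE)
  comp <- igraph::components(g)$no
  chi <- v - e + f
  list(n_vertices = v, n_edges = e, n_faces = f, euler = chi,
       defect_index = (2 - chi) / 2, n_components = comp)
}

#' Combined per-subject topology quality index
#'
#' Sum of the left and right hemisphere defect counts; higher = worse.
#'
#' @param lh_defects,rh_defects Non-negative per-hemisphere defect
#'   indices (from [mesh_topology()]`$defect_index`).
#' @return Combined index (higher = worse).
#' @export
subject_euler_index <- function(lh_defects, rh_defects) {
  if (any(c(lh_defects, rh_defects) < 0))
    stop("defect indices must be non-negative", call. = FALSE)
  lh_defects + rh_defects
}

#' Harmonize externally supplied signed Euler numbers
#'
#' FreeSurfer reports the signed Euler characteristic per hemisphere
#' (2 for a perfect sphere, lower with each defect: `chi = 2 - 2d`).
#' This maps a pair of signed values to the same higher-is-worse
#' combined defect index as [subject_euler_index()].
#'
#' @param lh_euler,rh_euler Signed per-hemisphere Euler characteristics.
#' @export
harmonize_euler <- function(lh_euler, rh_euler) {
  (2 - lh_euler) / 2 + (2 - rh_euler) / 2
}

#' Median absolute deviation
#'
#' `median(|x - median(x)|) * scale_constant`. The default scale
#' constant is 1 (raw MAD); 1.4826 makes the MAD a consistent estimator
#' of the standard deviation under normality.
#'
#' @param values Numeric vector with at least one finite value.
#' @param scale_constant Multiplier, default 1.0.
#' @export
mad_value <- function(values, scale_constant = 1.0) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values", call. = FALSE)
  stats::median(abs(values - stats::median(values))) * scale_constant
}

#' MAD-based quality thresholds
#'
#' Thresholds at `median + k * MAD` for each `k`, optionally computed
#' within groups (e.g. per acquisition site, where scanner differences
#' shift the whole quality distribution).
#'
#' @param values Numeric metric values (higher = worse).
#' @param k_list Positive MAD multiples, e.g. `c(1, 1.5, 2, 2.5, 3)`.
#' @param scale_constant Passed to [mad_value()].
#' @param groups Optional grouping vector aligned with `values`.
#' @return Named numeric vector of ascending thresholds, or (grouped) a
#'   data.frame with columns `group`, `k`, `threshold`.
#' @export
mad_thresholds <- function(values, k_list, scale_constant = 1.0,
                           groups = NULL) {
  if (!length(k_list) || any(k_list <= 0))
    stop("k_list must be non-empty and positive", call. = FALSE)
  k_list <- sort(k_list)
  if (is.null(groups)) {
    med <- stats::median(values, na.rm = TRUE)
    md <- mad_value(values, scale_constant)
    stats::setNames(med + k_list * md, paste0("k", k_list))
  } else {
    parts <- split(values, groups)
    out <- Map(function(v, g) {
      data.frame(group = g, k = k_list,
                 threshold = unname(mad_thresholds(v, k_list,
                                                   scale_constant)),
                 stringsAsFactors = FALSE)
    }, parts, names(parts))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  }
}

#' Filter a cohort by a quality cutoff
#'
#' Excludes participants whose quality is strictly worse than the
#' cutoff under the metric's declared direction (for a higher-is-worse
#' metric, values > cutoff are excluded and boundary values retained);
#' `strict_retention = TRUE` flips to excluding values >= cutoff.
#'
#' Modes: `absolute` (cutoff on the metric scale), `mad_k` (cutoff =
#' median + k * MAD of the metric column, `cutoff` giving k),
#' `top_fraction` (exclude the worst `cutoff` fraction), and
#' `median_split` (no exclusion; adds a `quality_group` column,
#' `"high"`/`"low"` quality, ties going to the better-quality group).
#'
#' @param cohort A [cohort_table].
#' @param metric A [qc_metric] or metric column name.
#' @param cutoff Cutoff value, MAD multiple, or fraction per `mode`.
#' @param mode One of `"absolute"`, `"mad_k"`, `"top_fraction"`,
#'   `"median_split"`.
#' @param per_site Compute `mad_k` / `top_fraction` cutoffs within site.
#' @param scale_constant MAD scale constant for `mad_k`.
#' @param strict_retention Exclude boundary values too.
#' @return List: `cohort` (filtered, or labelled for `median_split`)
#'   and `report` (n excluded overall, by site and by diagnosis, and
#'   the cutoff(s) applied).
#' @export
apply_quality_filter <- function(cohort, metric, cutoff,
                                 mode = c("absolute", "mad_k",
                                          "top_fraction", "median_split"),
                                 per_site = FALSE, scale_constant = 1.0,
                                 strict_retention = FALSE) {
  mode <- match.arg(mode)
  metric <- as_qc_metric(metric)
  if (!metric$name %in% names(cohort))
    stop("metric column not found: ", metric$name, call. = FALSE)
  x <- cohort[[metric$name]]
  # orient so that higher = worse for the exclusion rule
  worse <- if (metric$direction == "higher_worse") x else -x
  if (mode == "median_split") {
    med <- stats::median(worse, na.rm = TRUE)
    grp <- ifelse(worse <= med, "low", "high") # low = better quality
    out <- cohort
    out$quality_group <- grp
    return(list(cohort = out,
                report = list(mode = mode, median = med,
                              n_low = sum(grp == "low"),
                              n_high = sum(grp == "high"))))
  }
  cut_for <- function(w) {
    switch(mode,
           absolute = if (metric$direction == "higher_worse") cutoff
                      else -cutoff,
           mad_k = stats::median(w, na.rm = TRUE) +
             cutoff * mad_value(w, scale_constant),
           top_fraction = {
             if (cutoff < 0 || cutoff >= 1)
               stop("top_fraction cutoff must be in [0, 1)", call. = FALSE)
             stats::quantile(w, probs = 1 - cutoff, na.rm = TRUE,
                             names = FALSE, type = 7)
           })
  }
  if (per_site && mode %in% c("mad_k", "top_fraction")) {
    cuts <- tapply(worse, cohort$site, cut_for)
    cvec <- cuts[as.character(cohort$site)]
  } else {
    cvec <- rep(cut_for(worse), nrow(cohort))
  }
  keep <- if (strict_retention) worse < cvec else worse <= cvec
  keep[is.na(keep)] <- FALSE
  excl <- cohort[!keep, , drop = FALSE]
  list(cohort = cohort[keep, , drop = FALSE],
       report = list(mode = mode, cutoff = cutoff,
                     cutoff_applied = if (per_site) cvec[!duplicated(cohort$site)]
                                      else cvec[1],
                     n_retained = sum(keep), n_excluded = sum(!keep),
                     by_site = table(excl$site),
                     by_diagnosis = table(excl$diagnosis)))
}
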