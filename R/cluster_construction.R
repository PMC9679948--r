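# Construction and validation of the two keystroke clusters.
#
# Concept groups: timing features {PPL, RRL, HT, FT} are candidates for the
# fine motor score cluster (FMSC); error-related and paralinguistic features
# {preCS, CD, postCS, APP} are candidates for the cognition score cluster
# (CSC). A candidate enters the final cluster only if (a) it sits in the
# largest candidate subset whose pairwise Pearson correlations on the pooled
# subject-day matrix all exceed r_min (strict inequality, default 0.50), and
# (b) it contributes comparably to the first principal component of the
# standardized candidate matrix: |loading| >= tau * max|loading| (default
# tau = 0.7) with the majority loading sign.

#' Candidate features per cluster concept group
#' @return Named list with `FMSC` and `CSC` candidate feature sets.
#' @export
cluster_candidates <- function() {
  list(FMSC = c("PPL", "RRL", "HT", "FT"),
       CSC = c("preCS", "CD", "postCS", "APP"))
}

#' Define a keystroke cluster
#'
#' @param name Cluster name (`"FMSC"` or `"CSC"` in the default pipeline).
#' @param members Member feature codes (subset of `candidates`).
#' @param candidates Candidate feature codes.
#' @param window_half_width_days Half-width of the visit aggregation window
#'   in days (14 for FMSC, 7 for CSC).
#' @return An object of class `cluster_definition`.
#' @export
cluster_definition <- function(name, members, candidates = members,
                               window_half_width_days) {
  stopifnot(is.character(name), length(name) == 1L,
            length(members) >= 1L, all(members %in% candidates),
            is.numeric(window_half_width_days), window_half_width_days >= 0)
  structure(
    list(name = name, members = members, candidates = candidates,
         window_half_width_days = window_half_width_days),
    class = "cluster_definition"
  )
}

#' @export
print.cluster_definition <- function(x, ...) {
  cat(sprintf("<cluster %s> members: {%s} of {%s}; window: +/-%d days\n",
              x$name, paste(x$members, collapse = ", "),
              paste(x$candidates, collapse = ", "),
              as.integer(x$window_half_width_days)))
  invisible(x)
}

.complete_numeric_matrix <- function(x) {
  x <- as.data.frame(x)
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  as.matrix(x[complete.cases(x), , drop = FALSE])
}

#' Pairwise-correlation screen for cluster candidates
#'
#' Retains the largest candidate subset in which every pairwise Pearson
#' correlation (pooled over subject-days) strictly exceeds `r_min`; ties
#' between equally large subsets are broken by the higher mean pairwise
#' correlation. A single feature trivially coheres. Constant columns have no
#' defined correlation and are dropped with a warning.
#'
#' @param x Subject-day by candidate-feature matrix (or data frame); rows
#'   with missing values are ignored; at least 3 complete rows required.
#' @param r_min Correlation threshold (default 0.50, strict `>`).
#' @param groups Optional grouping vector (e.g. subject ids) aligned with the
#'   rows of `x`: correlations are then computed within each group and
#'   averaged across groups (groups with fewer than 3 complete rows are
#'   skipped), a sensitivity alternative to the default pooled correlation.
#' @return List with `retained` (feature names), `correlations` (the full
#'   correlation matrix), `r_min` and `dropped_constant`.
#' @export
correlation_screen <- function(x, r_min = 0.50, groups = NULL) {
  xdf <- as.data.frame(x)
  keep_rows <- complete.cases(
    xdf[, vapply(xdf, is.numeric, logical(1)), drop = FALSE])
  m <- .complete_numeric_matrix(x)
  if (nrow(m) < 3L) stop("correlation screen needs >= 3 complete rows",
                         call. = FALSE)
  sds <- apply(m, 2L, sd)
  dropped <- colnames(m)[!is.finite(sds) | sds == 0]
  if (length(dropped) > 0L) {
    warning("constant column(s) dropped from correlation screen: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    m <- m[, setdiff(colnames(m), dropped), drop = FALSE]
  }
  p <- ncol(m)
  if (p == 0L) stop("no non-constant candidate columns", call. = FALSE)
  if (is.null(groups)) {
    cm <- cor(m)
  } else {
    stopifnot(length(groups) == nrow(xdf))
    g <- as.character(groups)[keep_rows]
    mats <- lapply(split(seq_len(nrow(m)), g), function(idx) {
      if (length(idx) < 3L) return(NULL)
      sub <- m[idx, , drop = FALSE]
      if (any(apply(sub, 2L, sd) == 0)) return(NULL)
      cor(sub)
    })
    mats <- mats[!vapply(mats, is.null, logical(1))]
    if (length(mats) == 0L) {
      stop("no group has >= 3 complete non-constant rows", call. = FALSE)
    }
    cm <- Reduce(`+`, mats) / length(mats)
  }
  best <- NULL
  best_score <- -Inf
  for (size in seq(p, 1L)) {
    for (idx in utils::combn(p, size, simplify = FALSE)) {
      sub <- cm[idx, idx, drop = FALSE]
      off <- sub[upper.tri(sub)]
      if (all(off > r_min)) {
        # score singletons by their mean correlation with all candidates so
        # the tie-break stays deterministic and data-driven
        score <- if (length(off) > 0L) mean(off) else
          mean(cm[idx, -idx])
        if (is.null(best) || length(idx) > length(best) ||
            (length(idx) == length(best) && score > best_score)) {
          best <- idx
          best_score <- score
        }
      }
    }
    if (!is.null(best)) break
  }
  list(retained = colnames(m)[best], correlations = cm, r_min = r_min,
       dropped_constant = dropped)
}

#' First-principal-component contribution screen
#'
#' Computes loadings on the first principal component of the column-
#' standardized candidate matrix (correlation-matrix PCA). A feature
#' "contributes equally" when its absolute loading is at least
#' `tau * max(|loading|)` and its loading carries the majority sign.
#' Zero-variance columns are excluded before the decomposition and fail the
#' screen.
#'
#' @inheritParams correlation_screen
#' @param tau Relative loading threshold in (0, 1] (default 0.7).
#' @return List with `loadings` (PC1), `pass` (named logical), `tau`,
#'   `excluded` (zero-variance columns).
#' @export
pca_screen <- function(x, tau = 0.7) {
  stopifnot(is.numeric(tau), tau > 0, tau <= 1)
  m <- .complete_numeric_matrix(x)
  if (nrow(m) < 3L) stop("PCA screen needs >= 3 complete rows", call. = FALSE)
  sds <- apply(m, 2L, sd)
  excluded <- colnames(m)[!is.finite(sds) | sds == 0]
  keep <- setdiff(colnames(m), excluded)
  if (length(keep) == 0L) stop("no non-constant candidate columns",
                               call. = FALSE)
  pc <- prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  l <- setNames(pc$rotation[, 1L], rownames(pc$rotation))
  maj <- sign(sum(sign(l)))
  if (maj == 0) maj <- sign(l[which.max(abs(l))])
  pass_kept <- abs(l) >= tau * max(abs(l)) & sign(l) == maj
  pass <- setNames(rep(FALSE, ncol(m)), colnames(m))
  pass[names(pass_kept)] <- pass_kept
  loadings <- setNames(rep(NA_real_, ncol(m)), colnames(m))
  loadings[names(l)] <- l
  list(loadings = loadings, pass = pass, tau = tau, excluded = excluded)
}

#' Build the FMSC and CSC cluster definitions from daily records
#'
#' Reshapes the daily feature records into a pooled subject-day matrix per
#' concept group, applies the correlation and PCA screens, and defines each
#' cluster as the intersection of the two screens' survivors. Memberships can
#' be pinned explicitly (bypassing the screens) to reproduce a fixed cluster
#' composition on any dataset.
#'
#' @param daily Daily records from [aggregate_daily()].
#' @param r_min Correlation threshold (strict `>`; default 0.50).
#' @param tau Relative PC1 loading threshold (default 0.7).
#' @param pinned Optional named list, e.g.
#'   `list(FMSC = c("PPL","RRL","FT"), CSC = c("preCS","postCS","APP"))`.
#' @param fmsc_half_width,csc_half_width Window half-widths in days.
#' @param correlation_scope `"pooled"` (default: one correlation matrix over
#'   all subject-days) or `"within_subject"` (per-subject correlations
#'   averaged across subjects, a sensitivity alternative).
#' @return List with elements `FMSC` and `CSC` ([cluster_definition()]s) and
#'   `report` (correlations, loadings and per-feature decisions).
#' @export
build_cluster_definitions <- function(daily, r_min = 0.50, tau = 0.7,
                                      pinned = NULL,
                                      fmsc_half_width = 14,
                                      csc_half_width = 7,
                                      correlation_scope = c("pooled",
                                                            "within_subject")) {
  correlation_scope <- match.arg(correlation_scope)
  cand <- cluster_candidates()
  half <- c(FMSC = fmsc_half_width, CSC = csc_half_width)
  dt <- as.data.table(daily)
  report <- list()
  defs <- lapply(names(cand), function(cl) {
    if (!is.null(pinned) && !is.null(pinned[[cl]])) {
      report[[cl]] <<- list(pinned = TRUE, members = pinned[[cl]])
      return(cluster_definition(cl, pinned[[cl]], cand[[cl]], half[[cl]]))
    }
    wide <- data.table::dcast(dt[feature %in% cand[[cl]]],
                              subject_id + date ~ feature,
                              value.var = "daily_value")
    mat <- wide[, intersect(cand[[cl]], names(wide)), with = FALSE]
    grp <- if (correlation_scope == "within_subject") wide$subject_id
    cs <- correlation_screen(mat, r_min = r_min, groups = grp)
    ps <- pca_screen(mat, tau = tau)
    members <- intersect(cs$retained, names(ps$pass)[ps$pass])
    if (length(members) == 0L) {
      stop("no ", cl, " feature passed both screens; review r_min/tau ",
           "or pin memberships", call. = FALSE)
    }
    report[[cl]] <<- list(pinned = FALSE, correlation = cs, pca = ps,
                          members = members)
    cluster_definition(cl, members, cand[[cl]], half[[cl]])
  })
  names(defs) <- names(cand)
  c(defs, list(report = report))
}
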