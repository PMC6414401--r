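#' Residual deformation of one subject from the population trajectory
#'
#' Registers the trajectory snapshot at the subject's (grid-snapped) EYO
#' onto the subject's mesh. The estimated initial momenta `alpha0`,
#' anchored at the snapshot's transported control points, parametrise the
#' subject-specific residual deformation; they are the signal analysed
#' downstream after parallel transport to the baseline space. The
#' registration reuses the trajectory's kernels and `gamma`.
#'
#' @param traj a `GeodesicTrajectory`.
#' @param subject_mesh `TriMesh` in the common frame.
#' @param eyo the subject's EYO (clamped to the trajectory span).
#' @param cfg a [match_config()] (default: the trajectory's own).
#' @param subject_id optional id carried into the record.
#' @return object of class `ResidualRecord`: `subject_id`, `eyo`,
#'   `grid_time_index` (1-based snapshot index), `alpha0` (n x 3),
#'   `data_term`, and `theta0` (`NULL` until filled by
#'   [jacobi_transport()]).
#' @export
compute_residual <- function(traj, subject_mesh, eyo, cfg = NULL,
                             subject_id = NA_character_) {
  cfg <- cfg %||% traj$cfg
  s <- trajectory_snap_index(traj, eyo)
  snap_mesh <- traj$snapshots[[s]]
  cps <- traj$states[[s]]$points
  reg <- tryCatch(register(snap_mesh, subject_mesh, cps, cfg),
                  error = function(e)
                    stop("residual registration failed for subject '",
                         subject_id, "': ", conditionMessage(e)))
  structure(list(subject_id = subject_id, eyo = eyo, grid_time_index = s,
                 alpha0 = reg$system$momenta,
                 data_term = reg$diagnostics$data_term,
                 theta0 = NULL),
            class = "ResidualRecord")
}

#' Residual deformations for a whole cohort
#'
#' @param traj a `GeodesicTrajectory`.
#' @param meshes list of `TriMesh` (one per subject, common frame).
#' @param eyos matching EYO values.
#' @param cfg a [match_config()] (default: the trajectory's own).
#' @param subject_ids optional ids.
#' @return list of `ResidualRecord`.
#' @export
compute_residuals <- function(traj, meshes, eyos, cfg = NULL,
                              subject_ids = NULL) {
  subject_ids <- subject_ids %||% paste0("s", seq_along(meshes))
  lapply(seq_along(meshes), function(i)
    compute_residual(traj, meshes[[i]], eyos[i], cfg, subject_ids[i]))
}

#' Save / load a cohort's residual records
#'
#' One array container per cohort: `records.csv` stacks the per-subject
#' momenta row-wise (columns `subject_id`, `grid_time_index`, `row`,
#' `ax, ay, az` and, when transported, `tx, ty, tz`), and `meta.json`
#' records the per-subject EYO, data terms and counts.
#'
#' @param records list of `ResidualRecord`.
#' @param dir output directory.
#' @return `dir` invisibly (`save_residuals`) / the list of records
#'   (`load_residuals`).
#' @export
save_residuals <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stacks <- lapply(records, function(r) {
    n <- nrow(r$alpha0)
    df <- data.frame(subject_id = r$subject_id,
                     grid_time_index = r$grid_time_index,
                     row = seq_len(n),
                     ax = r$alpha0[, 1], ay = r$alpha0[, 2],
                     az = r$alpha0[, 3])
    if (!is.null(r$theta0)) {
      df$tx <- r$theta0[, 1]; df$ty <- r$theta0[, 2]; df$tz <- r$theta0[, 3]
    }
    df
  })
  write.csv(do.call(rbind, stacks), file.path(dir, "records.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    lapply(records, function(r)
      list(subject_id = r$subject_id, eyo = r$eyo,
           grid_time_index = r$grid_time_index, data_term = r$data_term,
           transported = !is.null(r$theta0))),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_residuals
#' @export
load_residuals <- function(dir) {
  df <- read.csv(file.path(dir, "records.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = FALSE)
  lapply(meta, function(m) {
    rows <- df[df$subject_id == m$subject_id, , drop = FALSE]
    rows <- rows[order(rows$row), , drop = FALSE]
    structure(list(subject_id = m$subject_id, eyo = m$eyo,
                   grid_time_index = as.integer(m$grid_time_index),
                   alpha0 = unname(as.matrix(rows[, c("ax", "ay", "az")])),
                   data_term = m$data_term,
                   theta0 = if (isTRUE(m$transported))
                     unname(as.matrix(rows[, c("tx", "ty", "tz")]))
                   else NULL),
              class = "ResidualRecord")
  })
}
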