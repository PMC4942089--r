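#' Run a batch of replicate simulations
#'
#' Repeats [run_simulation()] with seeds `seed_base + 1:reps` and collects
#' one summary row per replicate.
#'
#' @param config An `ms_config`, or a scenario name passed to
#'   [build_scenario()].
#' @param reps Number of replicates (the assays use 20).
#' @param seed_base Base seed; replicate i uses `seed_base + i`.
#' @param overrides Overrides when `config` is a scenario name.
#' @param keep_results Keep the full `ms_result` objects (memory-heavy).
#' @return An `ms_batch`: data frame `replicates` (seed, success,
#'   mating_time, partner ids, projection lengths, direction angles) plus
#'   the config and optionally `results`.
#' @export
run_batch <- function(config, reps = 20, seed_base = 0, overrides = list(),
                      keep_results = FALSE) {
  if (is.character(config)) config <- build_scenario(config, overrides)
  rows <- vector("list", reps)
  results <- if (keep_results) vector("list", reps) else NULL
  for (i in seq_len(reps)) {
    r <- run_simulation(config, seed = seed_base + i)
    dp <- tryCatch(direction_pair(r), error = function(e)
      list(theta_alpha = NA_real_, theta_a = NA_real_))
    pl <- projection_lengths_final(r)
    rows[[i]] <- data.frame(
      seed = seed_base + i, success = r$success,
      mating_time = r$mating_time,
      partner_a = r$partner[1], partner_alpha = r$partner[2],
      theta_alpha = dp$theta_alpha, theta_a = dp$theta_a,
      proj_len_a = pl["a"], proj_len_alpha = pl["alpha"],
      stringsAsFactors = FALSE)
    if (keep_results) results[[i]] <- r
  }
  structure(list(replicates = do.call(rbind, rows), config = config,
                 results = results), class = "ms_batch")
}

projection_lengths_final <- function(result) {
  pa <- pal <- NA_real_
  for (fc in result$final_curves) {
    r <- sqrt((fc$points[, 1] - fc$center0[1])^2 +
                (fc$points[, 2] - fc$center0[2])^2)
    pl <- max(max(r) - 1, 0)
    if (fc$type == "a" && is.na(pa)) pa <- pl
    if (fc$type == "alpha" && is.na(pal)) pal <- pl
  }
  c(a = pa, alpha = pal)
}

#' Mating efficiency of a batch
#'
#' The fraction of replicate simulations meeting the mating-success
#' criterion, with the mean and standard deviation of successful mating
#' times.
#'
#' @param batch An `ms_batch` (or its `replicates` data frame).
#' @return List: `n_reps`, `n_success`, `efficiency`, `mean_time`, `sd_time`.
#' @export
mating_efficiency <- function(batch) {
  df <- if (inherits(batch, "ms_batch")) batch$replicates else batch
  if (is.null(df) || nrow(df) == 0) stop("empty batch")
  succ <- df$success
  tt <- df$mating_time[succ]
  list(n_reps = nrow(df), n_success = sum(succ),
       efficiency = mean(succ),
       mean_time = if (any(succ)) mean(tt) else NA_real_,
       sd_time = if (sum(succ) > 1) stats::sd(tt) else NA_real_)
}

#' Projection-direction pair of one simulation
#'
#' The direction of each cell's projection relative to the partner axis,
#' averaged over the 50-s samples after polarisation. The alpha-cell angle
#' is counted counterclockwise and the a-cell angle clockwise, both in
#' \eqn{[-\pi/2, \pi/2]}, so that equal angles mean the projections point at
#' each other (the diagonal of the direction plot).
#'
#' @param result An `ms_result` from a scenario with one a- and one
#'   alpha-cell (for multi-alpha scenarios pass `alpha_id`).
#' @param alpha_id Optional id of the alpha-cell to use as partner; defaults
#'   to the mated partner or the first producer.
#' @return List with `theta_alpha`, `theta_a` (radians).
#' @export
direction_pair <- function(result, alpha_id = NULL) {
  s <- result$samples
  cells <- result$config$cells
  types <- vapply(cells, `[[`, "", "type")
  a_cell <- cells[[which(types == "a")[1]]]
  if (is.null(alpha_id)) {
    alpha_id <- if (!is.na(result$partner[2])) result$partner[2] else {
      al <- cells[types == "alpha"]
      prod <- vapply(al, function(cl) isTRUE(cl$producer), logical(1))
      al[[if (any(prod)) which(prod)[1] else 1L]]$id
    }
  }
  al_cell <- cells[[which(vapply(cells, `[[`, "", "id") == alpha_id)]]
  ang_of <- function(cell, partner_center, clockwise) {
    ss <- s[s$cell_id == cell$id & s$pol_found, ]
    if (nrow(ss) == 0) stop("no polarisome samples for cell ", cell$id)
    axis <- partner_center - cell$center
    axis <- axis / sqrt(sum(axis^2))
    dx <- ss$pol_x - cell$center[1]
    dy <- ss$pol_y - cell$center[2]
    # signed angle from the partner axis, counterclockwise positive
    th <- atan2(axis[1] * dy - axis[2] * dx, axis[1] * dx + axis[2] * dy)
    if (clockwise) th <- -th
    mean(th)
  }
  list(theta_alpha = ang_of(al_cell, a_cell$center, clockwise = FALSE),
       theta_a = ang_of(a_cell, al_cell$center, clockwise = TRUE))
}

#' Mean deviation of direction pairs from the diagonal
#'
#' In the direction plot each simulation is a point
#' \eqn{(\theta_\alpha, \theta_a)}; partners pointing at each other lie on
#' the identity diagonal. The deviation of one point is its perpendicular
#' distance to the diagonal, \eqn{|\theta_a - \theta_\alpha| / \sqrt 2};
#' the batch deviation is the mean over simulations.
#'
#' @param batch An `ms_batch`, its replicates data frame, or a two-column
#'   matrix of (theta_alpha, theta_a) pairs.
#' @param successful_only Use only successful replicates (default TRUE when
#'   success information is present).
#' @export
diagonal_deviation <- function(batch, successful_only = TRUE) {
  if (inherits(batch, "ms_batch")) batch <- batch$replicates
  if (is.matrix(batch)) {
    th_a <- batch[, 2]; th_al <- batch[, 1]
  } else {
    df <- batch
    if (successful_only && "success" %in% names(df)) df <- df[df$success, ]
    th_a <- df$theta_a; th_al <- df$theta_alpha
  }
  ok <- is.finite(th_a) & is.finite(th_al)
  if (!any(ok)) return(NA_real_)
  mean(abs(th_a[ok] - th_al[ok])) / sqrt(2)
}

#' Mating discrimination of a batch
#'
#' Among successful matings, the fraction in which the a-cell mated with the
#' designated pheromone-producing alpha-cell.
#'
#' @param batch An `ms_batch`.
#' @param producer_id Id of the producer alpha-cell; defaults to the first
#'   producer in the scenario.
#' @return List: `n_success`, `n_correct`, `discrimination` (NA when no
#'   successes), plus the mating-location table (`locations`).
#' @export
mating_discrimination <- function(batch, producer_id = NULL) {
  df <- batch$replicates
  cells <- batch$config$cells
  if (is.null(producer_id)) {
    al <- Filter(function(cl) cl$type == "alpha" && isTRUE(cl$producer), cells)
    if (length(al) == 0) stop("scenario has no producer alpha-cell")
    producer_id <- al[[1]]$id
  }
  succ <- df[df$success, , drop = FALSE]
  n_corr <- sum(succ$partner_alpha == producer_id)
  list(n_success = nrow(succ), n_correct = n_corr,
       discrimination = if (nrow(succ) > 0) n_corr / nrow(succ) else NA_real_,
       producer_id = producer_id,
       locations = succ[, c("seed", "partner_alpha", "mating_time")])
}

#' Competition outcome between two a-cell genotypes
#'
#' For scenarios with two a-cells and one alpha-cell: tallies which a-cell
#' won the alpha-cell per replicate. Ties (both a-cells satisfying the
#' success criterion at the same sample) are reported separately.
#'
#' @param batch An `ms_batch` from e.g. the `three_cell_compete` scenario.
#' @return Named list of win counts per a-cell id, plus `ties` and
#'   `no_mating`.
#' @export
competition_outcome <- function(batch) {
  df <- batch$replicates
  cells <- batch$config$cells
  a_ids <- vapply(Filter(function(cl) cl$type == "a", cells), `[[`, "", "id")
  wins <- stats::setNames(integer(length(a_ids)), a_ids)
  ties <- 0L; none <- 0L
  for (i in seq_len(nrow(df))) {
    if (!df$success[i]) { none <- none + 1L; next }
    w <- df$partner_a[i]
    if (w %in% names(wins)) wins[w] <- wins[w] + 1L
  }
  c(as.list(wins), list(ties = ties, no_mating = none))
}

#' Fisher's exact test on a 2x2 mating table
#'
#' Thin wrapper over [stats::fisher.test()] for comparing two mating
#' proportions (e.g. successes out of 20 under two conditions), with the
#' sidedness conventions used in the assays: one-sided "greater" for
#' directional hypotheses such as Bar1+ efficiency exceeding bar1-delta,
#' two-sided otherwise.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param alternative "two.sided", "greater" or "less" (group 1 vs group 2).
#' @return The p-value.
#' @export
fisher_mating_test <- function(x1, n1, x2, n2,
                               alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2,
            x1 == round(x1), x2 == round(x2), n1 == round(n1), n2 == round(n2))
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' @exportS3Method base::print
print.ms_batch <- function(x, ...) {
  me <- mating_efficiency(x)
  cat(sprintf("<ms_batch %s: %d/%d mated (ME %.2f)%s>\n",
              x$config$name, me$n_success, me$n_reps, me$efficiency,
              if (!is.na(me$mean_time))
                sprintf(", mean time %.0f +- %.0f s", me$mean_time,
                        ifelse(is.na(me$sd_time), 0, me$sd_time)) else ""))
  invisible(x)
}
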