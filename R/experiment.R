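#' Simulate a group of subjects
#'
#' Trains `n_subjects` independently built subjects for `n_sessions` each;
#' subject `k` uses seed `base_seed + k`, which drives both its sampled
#' parameters and its noise. Default base seeds differ between groups
#' (1000 control, 2000 ASD) so the two samples are independent.
#'
#' @param group `"control"` or `"asd"`.
#' @param n_subjects number of simulated children (default 15).
#' @param base_seed integer; subject `k` is seeded `base_seed + k`.
#' @param n_sessions training sessions per subject (default 10).
#' @param dt simulation step, ms.
#' @param .progress print one line per subject.
#' @return An object of class `debc_group`: `metrics` (tibble `subject`,
#'   `seed`, `session`, read-outs and weight means), `group`, `base_seed`.
#' @export
run_group <- function(group = c("control", "asd"), n_subjects = 15,
                      base_seed = if (match.arg(group) == "control") 1000 else 2000,
                      n_sessions = 10, dt = 0.1, .progress = FALSE) {
  group <- match.arg(group)
  metrics <- purrr::map_dfr(seq_len(n_subjects), function(k) {
    if (.progress) message(sprintf("%s subject %d/%d", group, k, n_subjects))
    tr <- run_training(group, seed = base_seed + k, n_sessions = n_sessions,
                       dt = dt)
    dplyr::mutate(tr$sessions, subject = k, seed = base_seed + k, .before = 1)
  })
  structure(list(metrics = metrics, group = group, base_seed = base_seed),
            class = "debc_group")
}

#' @export
print.debc_group <- function(x, ...) {
  cat(sprintf("<debc_group %s: %d subjects x %d sessions (base seed %d)>\n",
              x$group, dplyr::n_distinct(x$metrics$subject),
              max(x$metrics$session), x$base_seed))
  invisible(x)
}

#' @rdname run_group
#' @param x a `debc_group` object.
#' @param ... unused.
#' @method tidy debc_group
#' @export
tidy.debc_group <- function(x, ...) {
  dplyr::mutate(x$metrics, group = x$group, .before = 1)
}

#' Mann-Whitney U test between two samples
#'
#' Two-sided rank-sum test: exact null distribution for small untied
#' samples, normal approximation with continuity and tie correction
#' otherwise. Direction reports which sample has the higher median. Two
#' identical constant samples carry no ordering information and return
#' `p = 1`.
#'
#' @param x,y numeric samples (non-empty; `NA`s dropped).
#' @param alternative only `"two.sided"` is offered.
#' @return A one-row tibble: `U` (statistic for `x`), `p_value`,
#'   `direction` (`"x"`, `"y"` or `"tie"`), `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("samples must be non-empty")
  if (length(unique(c(x, y))) == 1) {
    return(tibble::tibble(U = length(x) * length(y) / 2, p_value = 1,
                          direction = "tie",
                          n_x = length(x), n_y = length(y)))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = !ties && (length(x) + length(y)) <= 50,
                       correct = TRUE)
  )
  mx <- stats::median(x); my <- stats::median(y)
  tibble::tibble(
    U = unname(wt$statistic),
    p_value = min(wt$p.value, 1),
    direction = if (mx > my) "x" else if (my > mx) "y" else "tie",
    n_x = length(x), n_y = length(y)
  )
}

#' Per-session group comparison
#'
#' Applies the two-sided Mann-Whitney U test to one read-out, session by
#' session, with no multiple-comparison correction. Subjects with a
#' missing value (e.g. peak latency of an all-zero trace) are excluded
#' from that session's samples.
#'
#' @param a,b [run_group()] results with equal session counts.
#' @param metric read-out column: `"cr_rate"`, `"peak_latency"`,
#'   `"dn_max_fr"` or `"dn_peak_time"`.
#' @return A tibble with one row per session: `session`, `U`, `p_value`,
#'   `direction` (`"a"`, `"b"` or `"tie"`, by group median), sample sizes.
#' @export
compare_groups <- function(a, b, metric = c("cr_rate", "peak_latency",
                                            "dn_max_fr", "dn_peak_time")) {
  metric <- match.arg(metric)
  stopifnot(inherits(a, "debc_group"), inherits(b, "debc_group"))
  sa <- sort(unique(a$metrics$session))
  sb <- sort(unique(b$metrics$session))
  if (!identical(sa, sb)) stop("groups have different session counts")
  purrr::map_dfr(sa, function(s) {
    va <- a$metrics[[metric]][a$metrics$session == s]
    vb <- b$metrics[[metric]][b$metrics$session == s]
    res <- mann_whitney_u(va, vb)
    tibble::tibble(
      session = s, U = res$U, p_value = res$p_value,
      direction = c(x = "a", y = "b", tie = "tie")[[res$direction]],
      n_a = res$n_x, n_b = res$n_y
    )
  })
}

#' Run the full two-group experiment
#'
#' Simulates the control and ASD groups and computes the per-session
#' Mann-Whitney comparisons for all four read-outs. This reproduces, at the
#' configured scale, the behavioural contrast of interest: a higher
#' conditioned-response rate in the ASD group during early sessions
#' (driven by the reduced Purkinje count disinhibiting the dentate nuclei
#' sooner) and an earlier CR peak throughout (driven by the halved
#' cerebello-cortical delays).
#'
#' @param n_subjects subjects per group (default 15).
#' @param base_seed_control,base_seed_asd group base seeds.
#' @param n_sessions sessions per subject (default 10).
#' @param dt simulation step, ms.
#' @param .progress print progress lines.
#' @return An object of class `debc_experiment`: `control` and `asd`
#'   [run_group()] results plus `comparisons`, a tibble with one row per
#'   (metric, session).
#' @export
run_experiment <- function(n_subjects = 15, base_seed_control = 1000,
                           base_seed_asd = 2000, n_sessions = 10, dt = 0.1,
                           .progress = FALSE) {
  control <- run_group("control", n_subjects, base_seed_control, n_sessions,
                       dt, .progress)
  asd <- run_group("asd", n_subjects, base_seed_asd, n_sessions, dt,
                   .progress)
  comparisons <- purrr::map_dfr(
    c("cr_rate", "peak_latency", "dn_max_fr", "dn_peak_time"),
    function(m) {
      dplyr::mutate(compare_groups(asd, control, m), metric = m, .before = 1)
    }
  )
  comparisons$direction <- c(a = "asd", b = "control",
                             tie = "tie")[comparisons$direction]
  structure(
    list(control = control, asd = asd, comparisons = comparisons),
    class = "debc_experiment"
  )
}

#' @export
print.debc_experiment <- function(x, ...) {
  cat("<debc_experiment>\n")
  print(glance(x))
  invisible(x)
}

#' @rdname run_experiment
#' @param x a `debc_experiment` object.
#' @param ... unused.
#' @method tidy debc_experiment
#' @export
tidy.debc_experiment <- function(x, ...) {
  dplyr::bind_rows(tidy(x$control), tidy(x$asd))
}

#' @rdname run_experiment
#' @method glance debc_experiment
#' @export
glance.debc_experiment <- function(x, ...) {
  cr <- x$comparisons[x$comparisons$metric == "cr_rate", ]
  pl <- x$comparisons[x$comparisons$metric == "peak_latency", ]
  tibble::tibble(
    n_control = dplyr::n_distinct(x$control$metrics$subject),
    n_asd = dplyr::n_distinct(x$asd$metrics$subject),
    n_sessions = max(cr$session),
    cr_max_p_sessions_1_6 = max(cr$p_value[cr$session <= 6]),
    cr_asd_higher_sessions_1_6 = all(cr$direction[cr$session <= 6] == "asd"),
    pl_max_p_all_sessions = max(pl$p_value),
    pl_asd_lower_all_sessions = all(pl$direction == "control")
  )
}

#' Plot group learning curves
#'
#' Session curves of a read-out: per-subject trajectories (thin) and the
#' group mean (thick), one colour per group.
#'
#' @param object a `debc_group` or `debc_experiment`.
#' @param metric read-out column to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot debc_experiment
#' @export
autoplot.debc_experiment <- function(object, metric = "cr_rate", ...) {
  df <- tidy(object)
  means <- df |>
    dplyr::group_by(.data$group, .data$session) |>
    dplyr::summarise(value = mean(.data[[metric]], na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$session, .data[[metric]],
                                   colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$group,
                                                        .data$subject)),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(y = .data$value), linewidth = 1.2) +
    ggplot2::scale_x_continuous(breaks = scales_breaks(df$session)) +
    ggplot2::labs(x = "training session", y = metric) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.debc_experiment
#' @method autoplot debc_group
#' @export
autoplot.debc_group <- function(object, metric = "cr_rate", ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$session, .data[[metric]],
                                   group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "training session", y = metric,
                  title = sprintf("%s group", object$group)) +
    ggplot2::theme_minimal()
}

scales_breaks <- function(x) sort(unique(x))
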