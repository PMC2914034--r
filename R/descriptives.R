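#' Two-sample comparison test
#'
#' Continuous variables are compared with the unequal-variance (Welch)
#' two-sample t-test; binary variables with the two-proportion z-test
#' using the pooled proportion, without continuity correction.  Both are
#' two-sided.  The choice of tests is a package convention - group
#' descriptive tables in this literature rarely name their tests - and is
#' stated here so agreement in kind is not mistaken for agreement in
#' method.
#'
#' @param values_a,values_b Numeric vectors (0/1 when `kind = "binary"`).
#' @param kind `"continuous"` or `"binary"`.
#' @return A list with `statistic` (t or z) and `p_value`.
#' @export
#' @examples
#' two_group_test(rnorm(50), rnorm(50), "continuous")$p_value
two_group_test <- function(values_a, values_b,
                           kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("Each group needs at least two observations.",
          class = "medchurn_validation_error")
  }
  if (kind == "continuous") {
    if (sd(values_a) == 0 && sd(values_b) == 0) {
      # degenerate but well-defined: identical constants differ by 0
      stat <- if (mean(values_a) == mean(values_b)) 0 else Inf
      return(list(statistic = stat,
                  p_value = if (stat == 0) 1 else 0))
    }
    ht <- t.test(values_a, values_b, var.equal = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    if (!all(c(values_a, values_b) %in% c(0, 1))) {
      abort("Binary test requires 0/1 values.",
            class = "medchurn_validation_error")
    }
    n1 <- length(values_a); n2 <- length(values_b)
    p1 <- mean(values_a); p2 <- mean(values_b)
    p_pool <- (sum(values_a) + sum(values_b)) / (n1 + n2)
    se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
    if (se == 0) return(list(statistic = 0, p_value = 1))
    z <- (p1 - p2) / se
    list(statistic = z, p_value = 2 * pnorm(-abs(z)))
  }
}

#' Group descriptive table by transition group
#'
#' Summarizes variables for the no-transition, single-transition and
#' multiple-transition groups, with two-sample p-values comparing each
#' transition group against the continuously enrolled (no-transition)
#' reference.  Time-constant covariates are summarized at the person
#' level; round-varying covariates and utilization counts at the
#' person-round level, so count means are per-round figures.  Binary
#' variables are reported as percentages (0-100) with the standard
#' deviation of the underlying indicator.
#'
#' @param panel A validated panel tibble.
#' @param variables Columns to summarize; defaults to the standard
#'   descriptive set (covariates then the four utilization counts).
#' @return A tibble with one row per variable: group means (or
#'   percentages), standard deviations, p-values for single-vs-none and
#'   multiple-vs-none, plus per-group person counts as attributes
#'   `n_none`, `n_single`, `n_multiple`.
#' @export
summarize_by_group <- function(panel,
                               variables = c("age", "male", "married",
                                             "high_school", "family_size",
                                             "white", "employed", "healthy",
                                             "income", "chronic_count",
                                             outcome_names())) {
  unknown <- setdiff(variables, names(panel))
  if (length(unknown) > 0) {
    abort(paste0("Unknown variable(s): ", paste(unknown, collapse = ", ")),
          class = "medchurn_validation_error")
  }
  prof <- transition_profiles(panel)
  df <- dplyr::left_join(panel, prof[c("person_id", "group")],
                         by = "person_id")
  person_level <- c("age", "male", "married", "high_school", "white",
                    "family_size", "chronic_count")
  binary_cols <- c("male", "married", "high_school", "white", "employed",
                   "healthy", "medicaid")

  counts <- table(prof$group)
  one_var <- function(v) {
    if (v %in% person_level) {
      d <- df[df$round == 1, c("group", v)]
    } else {
      d <- df[c("group", v)]
    }
    vals <- split(d[[v]], d$group)
    kind <- if (v %in% binary_cols) "binary" else "continuous"
    scale <- if (kind == "binary") 100 else 1
    stat <- function(x) {
      if (length(x) < 2) {
        warn(paste0("Group with fewer than 2 observations for `", v,
                    "`; dispersion reported as NA."))
        c(mean(x) * scale, NA_real_)
      } else {
        c(mean(x) * scale, sd(x))
      }
    }
    s0 <- stat(vals$none); s1 <- stat(vals$single); s2 <- stat(vals$multiple)
    p1 <- if (length(vals$none) >= 2 && length(vals$single) >= 2) {
      two_group_test(vals$single, vals$none, kind)$p_value
    } else NA_real_
    p2 <- if (length(vals$none) >= 2 && length(vals$multiple) >= 2) {
      two_group_test(vals$multiple, vals$none, kind)$p_value
    } else NA_real_
    tibble(variable = v, kind = kind,
           none = s0[1], sd_none = s0[2],
           single = s1[1], sd_single = s1[2], p_single = p1,
           multiple = s2[1], sd_multiple = s2[2], p_multiple = p2)
  }
  out <- purrr::list_rbind(purrr::map(variables, one_var))
  attr(out, "n_none") <- unname(counts["none"])
  attr(out, "n_single") <- unname(counts["single"])
  attr(out, "n_multiple") <- unname(counts["multiple"])
  out
}

#' Bar chart of the transition-group mix
#'
#' @param panel A validated panel tibble.
#' @return A ggplot showing the share of persons with no, one, and
#'   multiple Medicaid transitions.
#' @export
plot_transition_mix <- function(panel) {
  prof <- transition_profiles(panel)
  shares <- prof |>
    dplyr::count(.data$group) |>
    dplyr::mutate(share = 100 * .data$n / sum(.data$n))
  ggplot2::ggplot(shares, ggplot2::aes(x = .data$group, y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$share)),
                       vjust = -0.4) +
    ggplot2::labs(x = "Medicaid transitions over the panel",
                  y = "Share of persons (%)",
                  title = "Enrollment-stability groups")
}
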