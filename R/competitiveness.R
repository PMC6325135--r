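# Mate-competition model and the Fried competitiveness index.
#
# One-mating model: in a cage with n_wt fertile wild-type males and n_test
# sterile test males of relative competitiveness c, each female's single mate
# is a test male with probability c*n_test / (n_wt + c*n_test).  Eggs sired
# by fertile males hatch with probability h0, sterile-sired eggs with
# h_sterile (0 by default).

#' Expected egg-hatch probability under mate competition
#'
#' @param c relative mating competitiveness of test males (>= 0).
#' @param h0 hatch probability of fertile-sired eggs, in (0, 1].
#' @param n_wt,n_test numbers of wild-type and test males in the cage.
#' @param h_sterile hatch probability of sterile-sired eggs (default 0).
#' @return expected hatch probability
#'   `h0 * P(wt mate) + h_sterile * P(test mate)`.
#' @examples
#' expected_hatch(0.78, 0.851, 1, 1)  # ~0.478
#' @export
expected_hatch <- function(c, h0, n_wt, n_test, h_sterile = 0) {
  stopifnot(c >= 0, h0 > 0, h0 <= 1, h_sterile >= 0, h_sterile <= 1)
  denom <- n_wt + c * n_test
  if (any(denom == 0)) stop("n_wt + c * n_test must be positive")
  p_test <- c * n_test / denom
  h0 * (1 - p_test) + h_sterile * p_test
}

#' Fried competitiveness index
#'
#' Inverts [expected_hatch()]: given the hatch rate `h_mix` observed with
#' mixed males, the fertile-baseline hatch rate `h_ctrl`, and the male
#' ratio, the test males' relative competitiveness is
#' `c = (n_wt / n_test) * (h_ctrl - h_mix) / (h_mix - h_sterile)`.
#'
#' @param h_mix hatch rate in mixed-male cages.
#' @param h_ctrl hatch rate in the fertile-male control cages.
#' @param n_wt,n_test numbers of wild-type and test males in the mixed cages.
#' @param h_sterile hatch rate of sterile-sired eggs (default 0).
#' @return the competitiveness index `c` (clamped to 0, with a warning, when
#'   `h_mix > h_ctrl` would imply a negative index).
#' @examples
#' fried_index(0.479, 0.851)  # ~0.78
#' @export
fried_index <- function(h_mix, h_ctrl, n_wt = 1, n_test = 1, h_sterile = 0) {
  stopifnot(h_ctrl > 0, h_ctrl <= 1, n_wt > 0, n_test > 0)
  if (h_mix <= h_sterile) {
    stop("h_mix <= h_sterile: competitiveness index undefined")
  }
  if (h_mix > h_ctrl) {
    warning("h_mix exceeds h_ctrl; negative competitiveness clamped to 0")
    return(0)
  }
  (n_wt / n_test) * (h_ctrl - h_mix) / (h_mix - h_sterile)
}

#' Validate a competition-assay table
#'
#' Expected columns: `replicate`, `n_wt_males`, `n_test_males`, `n_females`,
#' `eggs_laid`, `eggs_hatched`.
#'
#' @param table a data.frame.
#' @return the table, invisibly; errors describe the first violation.
#' @export
validate_assay_table <- function(table) {
  need <- c("replicate", "n_wt_males", "n_test_males", "n_females",
            "eggs_laid", "eggs_hatched")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("assay table lacks columns: ", paste(missing, collapse = ", "))
  }
  counts <- c("n_wt_males", "n_test_males", "n_females", "eggs_laid",
              "eggs_hatched")
  if (any(unlist(table[counts]) < 0)) stop("assay counts must be >= 0")
  if (any(table$eggs_hatched > table$eggs_laid)) {
    stop("eggs_hatched exceeds eggs_laid in some row")
  }
  invisible(table)
}

#' Read a competition-assay CSV
#'
#' @param path path to a CSV with the [validate_assay_table()] columns.
#' @return a validated data.frame.
#' @export
read_assay_csv <- function(path) {
  validate_assay_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

pooled_hatch <- function(rows) {
  laid <- sum(rows$eggs_laid)
  if (laid == 0) stop("all-zero egg counts in a stratum")
  sum(rows$eggs_hatched) / laid
}

#' Estimate sterile-male competitiveness from an assay table
#'
#' Hatch rates are pooled (total hatched / total laid) within the mixed-male
#' stratum and the chosen control stratum, then inverted with
#' [fried_index()].  The default baseline is the two-wild-male control
#' (`baseline_rule = "two_wt"`), which isolates true competition from the
#' dilution effect of removing one fertile male; `"one_wt"` selects the
#' single-wild-male control instead and yields a different index — the two
#' are reported separately, never averaged.  Uncertainty comes from a
#' percentile bootstrap over replicates (each resampled replicate contributes
#' its mixed and control cages).
#'
#' @param table a [validate_assay_table()] data.frame containing mixed rows
#'   (`n_wt_males > 0` and `n_test_males > 0`) and control rows matching the
#'   baseline rule (`n_test_males = 0` with 2 or 1 wild males).
#' @param baseline_rule `"two_wt"` or `"one_wt"`.
#' @param n_boot bootstrap resamples (0 for plugin estimate only).
#' @param seed integer seed for the bootstrap.
#' @param h_sterile hatch rate of sterile-sired eggs (default 0).
#' @return an object of class `competitiveness_estimate` with `c_hat`,
#'   `ci_low`/`ci_high`/`sd` (when `n_boot > 0`), `method`, and the pooled
#'   stratum hatch rates.
#' @export
estimate_competitiveness <- function(table, baseline_rule = c("two_wt", "one_wt"),
                                     n_boot = 1000, seed = 1L, h_sterile = 0) {
  baseline_rule <- match.arg(baseline_rule)
  validate_assay_table(table)
  n_ctrl_males <- if (baseline_rule == "two_wt") 2 else 1
  is_mixed <- table$n_wt_males > 0 & table$n_test_males > 0
  is_ctrl <- table$n_test_males == 0 & table$n_wt_males == n_ctrl_males
  if (!any(is_mixed)) stop("no mixed-male rows in assay table")
  if (!any(is_ctrl)) {
    stop("no control rows with ", n_ctrl_males, " wild male(s) in assay table")
  }
  ratio <- unique(table$n_wt_males[is_mixed] / table$n_test_males[is_mixed])
  if (length(ratio) != 1) stop("mixed rows have inconsistent male ratios")

  plugin <- function(tab, warn = TRUE) {
    h_mix <- pooled_hatch(tab[tab$n_wt_males > 0 & tab$n_test_males > 0, ])
    h_ctrl <- pooled_hatch(tab[tab$n_test_males == 0 &
                                 tab$n_wt_males == n_ctrl_males, ])
    if (h_mix <= h_sterile) return(NA_real_)
    if (h_mix > h_ctrl) {
      if (warn) warning("h_mix exceeds h_ctrl; clamping index to 0")
      return(0)
    }
    ratio * (h_ctrl - h_mix) / (h_mix - h_sterile)
  }
  c_hat <- plugin(table)

  est <- structure(
    list(c_hat = c_hat, ci_low = NULL, ci_high = NULL, sd = NULL,
         method = "plugin", baseline_rule = baseline_rule,
         h_mix = pooled_hatch(table[is_mixed, ]),
         h_ctrl = pooled_hatch(table[is_ctrl, ]),
         n_boot = n_boot),
    class = "competitiveness_estimate"
  )
  if (n_boot > 0) {
    set.seed(seed)
    reps <- unique(table$replicate)
    # per-replicate stratum totals; a resample is then an index sum
    agg <- function(rows, col) {
      vapply(reps, function(id) sum(rows[[col]][rows$replicate == id]), 0)
    }
    mix_laid <- agg(table[is_mixed, ], "eggs_laid")
    mix_hatch <- agg(table[is_mixed, ], "eggs_hatched")
    ctl_laid <- agg(table[is_ctrl, ], "eggs_laid")
    ctl_hatch <- agg(table[is_ctrl, ], "eggs_hatched")
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(reps), length(reps), replace = TRUE)
      ml <- sum(mix_laid[idx]); cl <- sum(ctl_laid[idx])
      if (ml == 0 || cl == 0) return(NA_real_)
      h_mix <- sum(mix_hatch[idx]) / ml
      h_ctrl <- sum(ctl_hatch[idx]) / cl
      if (h_mix <= h_sterile) return(NA_real_)
      if (h_mix > h_ctrl) return(0)
      ratio * (h_ctrl - h_mix) / (h_mix - h_sterile)
    }, 0)
    boot <- boot[is.finite(boot)]
    if (length(boot) >= 2) {
      ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
      est$ci_low <- ci[1]
      est$ci_high <- ci[2]
      est$sd <- stats::sd(boot)
      est$method <- "bootstrap"
    }
  }
  est
}

#' @export
print.competitiveness_estimate <- function(x, ...) {
  cat(sprintf("Competitiveness index: %.3f (baseline %s, pooled h_mix %.3f, h_ctrl %.3f)\n",
              x$c_hat, x$baseline_rule, x$h_mix, x$h_ctrl))
  if (!is.null(x$ci_low)) {
    cat(sprintf("  95%% bootstrap CI [%.3f, %.3f], SD %.3f (%d resamples)\n",
                x$ci_low, x$ci_high, x$sd, x$n_boot))
  }
  invisible(x)
}
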