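#' Three-column regression table in IRR (SE) style
#'
#' Renders one outcome's fits across specifications as a table whose
#' cells are `IRR(SE)` with significance stars (`* p<0.10, ** p<0.05,
#' *** p<0.01`), IRRs at 4 significant digits and standard errors at 2,
#' the usual layout of published count-model tables.  Every number is
#' taken from the corresponding fit; no arithmetic beyond rounding
#' happens at the formatting stage.
#'
#' @param fits Named list of `mc_fit` objects (e.g. a `mc_spec_set`).
#' @return A tibble with `term` and one character column per fit, plus
#'   trailing rows for the log-likelihood, observations and persons.
#' @export
format_fit_table <- function(fits) {
  fits <- unclass(fits)
  cell <- function(fit, term) {
    i <- match(term, names(fit$coefficients))
    if (is.na(i)) return("")
    td <- tidy(fit)
    paste0(formatC(signif(td$irr[i], 4), format = "fg", flag = "#"),
           td$stars[i],
           "(", formatC(signif(td$irr.se[i], 2), format = "fg", flag = "#"),
           ")")
  }
  terms <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  body <- tibble(term = terms)
  for (nm in names(fits)) {
    body[[nm]] <- unname(vapply(terms, function(tm) cell(fits[[nm]], tm),
                                character(1)))
  }
  footer <- tibble(term = c("logLik", "observations", "persons"))
  for (nm in names(fits)) {
    f <- fits[[nm]]
    footer[[nm]] <- unname(c(formatC(f$loglik, format = "f", digits = 1),
                             as.character(f$n_obs),
                             as.character(f$n_persons)))
  }
  dplyr::bind_rows(body, footer)
}

resolve_input <- function(input, drop_incomplete = FALSE) {
  if (inherits(input, "sim_config")) {
    generate_dataset(input)$panel
  } else if (is.character(input) && length(input) == 1) {
    read_panel(input, drop_incomplete = drop_incomplete)
  } else if (is.data.frame(input)) {
    validate_panel(input, drop_incomplete = drop_incomplete)
  } else {
    abort("`input` must be a panel data frame, a CSV path, or a sim_config.",
          class = "medchurn_validation_error")
  }
}

#' Run the full churn-utilization analysis
#'
#' Orchestrates the pipeline: load or simulate the panel, build the
#' transition groups and descriptive table, fit the requested
#' specifications for each outcome, and (optionally) write the report
#' bundle: a descriptives table, one `IRR(SE)` regression table per
#' outcome, a machine-readable `results.json`, and a plain-text run log
#' recording sample sizes and row counts per specification.  Given the
#' same input and options the bundle is byte-identical across runs.
#'
#' A failed or non-converged fit for one outcome does not block the
#' others; it is recorded, and unless `allow_nonconverged = TRUE` the
#' function raises an error after writing everything it could.
#'
#' @param input A validated panel tibble, a CSV path, or a [sim_config()]
#'   (which is simulated first).
#' @param outcomes Count outcomes to analyze (default: all four).
#' @param specs Specifications to fit (default: all three).
#' @param mixing,h_form,quad_nodes Passed to the model builder and fitter.
#' @param out_dir Output directory for the report bundle; `NULL` (default)
#'   skips writing and just returns the bundle.
#' @param format `"tsv"` or `"md"` for the rendered tables.
#' @param allow_nonconverged Do not error when some fit fails to converge.
#' @param se Compute standard errors (needed for the tables).
#' @return Invisibly, a list with the panel, descriptives, fits (nested
#'   by outcome then spec), rendered tables, and the results list that
#'   `results.json` serializes.
#' @export
run_analysis <- function(input,
                         outcomes = outcome_names(),
                         specs = c("static1", "static2", "dynamic3"),
                         mixing = "gamma",
                         h_form = "identity",
                         quad_nodes = 20,
                         out_dir = NULL,
                         format = c("tsv", "md"),
                         allow_nonconverged = FALSE,
                         se = TRUE) {
  format <- match.arg(format)
  if (length(outcomes) < 1 || length(specs) < 1) {
    abort("At least one outcome and one specification are required.",
          class = "medchurn_config_error")
  }
  panel <- resolve_input(input)

  desc <- summarize_by_group(panel)
  fits <- list()
  failures <- character(0)
  for (oc in outcomes) {
    fits[[oc]] <- list()
    for (sp in specs) {
      res <- tryCatch(
        fit_re_poisson(build_model_frame(panel, oc, sp, h_form),
                       mixing = mixing, quad_nodes = quad_nodes, se = se),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures <- c(failures,
                      paste0(oc, "/", sp, ": ", conditionMessage(res)))
        fits[[oc]][[sp]] <- NULL
      } else {
        if (!res$converged) {
          failures <- c(failures, paste0(oc, "/", sp, ": did not converge"))
        }
        fits[[oc]][[sp]] <- res
      }
    }
  }

  tables <- purrr::map(fits, format_fit_table)

  results <- list(
    meta = list(
      package = "medchurn",
      version = as.character(utils::packageVersion("medchurn")),
      n_persons = n_persons(panel),
      n_rounds = n_rounds(panel),
      rows_static = n_persons(panel) * n_rounds(panel),
      rows_dynamic = n_persons(panel) * (n_rounds(panel) - 1),
      mixing = mixing,
      h_form = h_form,
      seed = if (inherits(input, "sim_config")) input$seed else NULL
    ),
    group_counts = as.list(table(transition_profiles(panel)$group)),
    descriptives = as.data.frame(desc),
    fits = purrr::map(fits, function(by_spec) {
      purrr::map(by_spec, function(f) {
        list(tidy = as.data.frame(tidy(f)), glance = as.data.frame(glance(f)))
      })
    }),
    failures = failures
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table <- function(tb, path) {
      if (format == "tsv") {
        readr::write_tsv(tb, paste0(path, ".tsv"), progress = FALSE)
      } else {
        writeLines(markdown_table(tb), paste0(path, ".md"))
      }
    }
    write_table(desc, file.path(out_dir, "descriptives"))
    for (oc in names(tables)) {
      write_table(tables[[oc]], file.path(out_dir, paste0("table_", oc)))
    }
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    log_lines <- c(
      paste0("medchurn ", utils::packageVersion("medchurn")),
      paste0("persons: ", n_persons(panel)),
      paste0("rounds: ", n_rounds(panel)),
      paste0("rows static: ", n_persons(panel) * n_rounds(panel)),
      paste0("rows dynamic: ", n_persons(panel) * (n_rounds(panel) - 1)),
      if (inherits(input, "sim_config")) paste0("seed: ", input$seed),
      paste0("outcomes: ", paste(outcomes, collapse = ", ")),
      paste0("specs: ", paste(specs, collapse = ", ")),
      paste0("mixing: ", mixing),
      if (length(failures) > 0) paste0("FAILED: ", failures)
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }

  if (length(failures) > 0 && !allow_nonconverged) {
    abort(paste0("Some fits failed or did not converge:\n  ",
                 paste(failures, collapse = "\n  ")),
          class = "medchurn_fit_error")
  }

  invisible(list(panel = panel, descriptives = desc, fits = fits,
                 tables = tables, results = results))
}

markdown_table <- function(tb) {
  tb <- dplyr::mutate(tb, dplyr::across(dplyr::everything(), as.character))
  header <- paste0("| ", paste(names(tb), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tb)), collapse = "|"), "|")
  rows <- apply(tb, 1, function(r) {
    paste0("| ", paste(ifelse(is.na(r), "", r), collapse = " | "), " |")
  })
  c(header, sep, rows)
}
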