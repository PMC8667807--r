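#' Full prediction report for one receptor composition
#'
#' Ties the modules together: parses the composition, computes its ring
#' charge, evaluates the complete displacement matrix (every entering ion
#' against every occupancy state, including the empty pore) and the per-ion
#' selectivity classes, and stamps the result with provenance (registry
#' version, alignment constants, optional seed). Every number in the report
#' is recomputed from the model on each call.
#'
#' @param composition Composition string or [receptor_assembly()].
#' @param ambient Ambient ion set; default Na+ and Ca2+.
#' @param hypothetical Allow non-tetramer assemblies.
#' @param seed Optional seed recorded in the provenance block (the report
#'   itself is deterministic).
#' @return A `prediction_report`: list with `composition`, `assembly`,
#'   `r_q`, `displacement` (data.frame `entering` x `resident` with the
#'   binary verdict and intermediates), `classes`
#'   ([classify_selectivity()] table), `model` (the occupancy model) and
#'   `provenance`.
#' @export
#' @examples
#' predict_report("GluN1/GluN2B/GluN3A/GluN2B")
predict_report <- function(composition, ambient = c("Na+", "Ca2+"),
                           hypothetical = FALSE, seed = NULL) {
  assembly <- parse_composition(composition, hypothetical = hypothetical)
  r <- assembly$ring
  ions <- vapply(lapply(ambient, as_ion), `[[`, "", "name")
  states <- c("EMPTY", ions)
  disp <- do.call(rbind, lapply(ions, function(i) {
    do.call(rbind, lapply(states, function(s) {
      v <- permeability(r, i, if (s == "EMPTY") "EMPTY" else s)
      data.frame(entering = i, resident = s, A = v$attractivity,
                 residual = v$residual_ring, B = v$inward_drive,
                 permeable = v$permeable, stringsAsFactors = FALSE)
    }))
  }))
  model <- build_occupancy_model(r, ions)
  structure(
    list(
      composition = paste(vapply(assembly$subunits, `[[`, "", "name"),
                          collapse = "/"),
      assembly = assembly,
      r_q = r,
      displacement = disp,
      classes = classify_selectivity(model),
      model = model,
      provenance = list(
        package = "ringcharge",
        registry_version = REGISTRY_VERSION,
        model = "charge-permeability (binary A x B)",
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
      )
    ),
    class = "prediction_report"
  )
}

#' @export
print.prediction_report <- function(x, explain = FALSE, ...) {
  cat("== ringcharge prediction ==\n")
  cat("composition:", x$composition, "\n")
  cat("ring charge r_q =", x$r_q, "\n\n")
  cat("displacement matrix (entering x resident):\n")
  print(x$displacement, row.names = FALSE)
  cat("\nselectivity classes:\n")
  print(x$classes, row.names = FALSE)
  if (explain) {
    cat("\nworking tables:\n")
    for (k in seq_len(nrow(x$displacement))) {
      row <- x$displacement[k, ]
      cat(sprintf("\n-- %s entering [%s] --\n", row$entering, row$resident))
      print(working_table(x$r_q, row$entering,
                          if (row$resident == "EMPTY") "EMPTY"
                          else row$resident),
            row.names = FALSE)
    }
  }
  cat(sprintf("\n(registry v%s; %s)\n", x$provenance$registry_version,
              x$provenance$model))
  invisible(x)
}

#' Serialize a prediction report to JSON
#'
#' @param report A [predict_report()] result.
#' @param pretty Pretty-print?
#' @return JSON string.
#' @export
report_json <- function(report, pretty = TRUE) {
  stopifnot(inherits(report, "prediction_report"))
  jsonlite::toJSON(
    list(
      composition = report$composition,
      r_q = report$r_q,
      displacement = report$displacement,
      classes = report$classes,
      transitions = report$model$edges,
      provenance = report$provenance
    ),
    auto_unbox = TRUE, pretty = pretty, dataframe = "rows", na = "null"
  )
}

#' Write a data.frame as TSV
#'
#' Thin wrapper fixing the conventions used across the package's table
#' outputs: tab separator, no quotes, no row names.
#'
#' @param x A data.frame.
#' @param path Output path or connection (`""` prints to stdout).
#' @export
write_tsv <- function(x, path = "") {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
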