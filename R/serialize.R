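#' Serialize a GRN model to JSON
#'
#' Writes `{method, n_genes, edges, params}` as structured text,
#' round-trip stable to full float precision (see [model_from_json()]).
#'
#' @param model a [grn_model()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  p <- model$params
  plist <- switch(model$method,
    ANN = list(v = p$v, theta = p$theta, k = p$k, w = p$w),
    SS = list(alpha = p$alpha, beta = p$beta, g = p$g, h = p$h),
    GRLOT = list(v = p$v, k = p$k, regulators = p$regulators))
  doc <- list(method = model$method,
              n_genes = model$topology$n_genes,
              edges = model$topology$edges,
              params = plist)
  # digits = I(17): enough significant digits for exact double round-trips
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           dataframe = "columns")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Read a GRN model back from its JSON serialization
#'
#' @param json a JSON string, or a path to a file written by
#'   [model_to_json()].
#' @return a [grn_model()].
#' @export
model_from_json <- function(json) {
  if (length(json) == 1L && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(json)
  edges <- as.data.frame(doc$edges)
  topo <- grn_topology(doc$n_genes, edges)
  p <- doc$params
  n <- topo$n_genes
  params <- switch(doc$method,
    ANN = ann_params(v = p$v, w = matrix(unlist(p$w), n, n),
                     theta = p$theta, k = p$k),
    SS = ss_params(alpha = p$alpha, beta = p$beta,
                   g = matrix(unlist(p$g), n, n),
                   h = matrix(unlist(p$h), n, n)),
    GRLOT = grlot_params(v = p$v, k = p$k,
                         regulators = as.data.frame(p$regulators)))
  grn_model(doc$method, topo, params)
}
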