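# Expectation sets: published or planted reference values stored as data
# (JSON), compared against freshly computed pipeline results. Quantities:
#   census_count    selector: {kind}
#   fret_rate       selector: {a, b}  (display labels, either order;
#   mg_distance                        several structural copies may match —
#                                      the pair closest to the expected value
#                                      is scored, since refined dimers are
#                                      never exactly symmetric)
#   contact_distance selector: {a, b} (display labels in the contact map)
#   layer_count     selector: {layer}
#   polar_distance  selector: {a, b}  ("chain:resnum[:atom]" selections)

#' Read an expectation set from JSON
#'
#' @param path JSON file: array of objects with fields `id`, `quantity`,
#'   `selector`, `expected`, `tolerance` (and optional `note`).
#' @return data.frame of class `expectation_set` (selectors as list column).
#' @export
read_expectations <- function(path) {
  if (!file.exists(path)) stop("expectations not found: ", path, call. = FALSE)
  e <- jsonlite::read_json(path, simplifyVector = FALSE)
  e <- e[["expectations"]] %||% e
  ids <- vapply(e, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("expectation ids must be unique: ", ids[duplicated(ids)][1L],
         call. = FALSE)
  out <- data.frame(
    id = ids,
    quantity = vapply(e, `[[`, character(1), "quantity"),
    expected = vapply(e, function(x) as.numeric(x$expected), numeric(1)),
    tolerance = vapply(e, function(x) as.numeric(x$tolerance), numeric(1)),
    stringsAsFactors = FALSE
  )
  out$selector <- lapply(e, `[[`, "selector")
  if (any(out$tolerance < 0))
    stop("expectation tolerances must be >= 0", call. = FALSE)
  class(out) <- c("expectation_set", class(out))
  out
}

supported_quantities <- function() {
  c("census_count", "fret_rate", "mg_distance", "contact_distance",
    "layer_count", "polar_distance")
}

# Edges whose display labels match {a, b} in either order.
match_edges <- function(edges, a, b) {
  hit <- (edges$donor_label == a & edges$acceptor_label == b) |
         (edges$donor_label == b & edges$acceptor_label == a)
  edges[hit, , drop = FALSE]
}

lookup_quantity <- function(quantity, selector, results) {
  switch(quantity,
    census_count = {
      k <- selector$kind
      if (is.null(results$census) || !k %in% names(results$census$counts))
        return(NA_real_)
      as.numeric(results$census$counts[[k]])
    },
    fret_rate = ,
    mg_distance = {
      if (is.null(results$network)) return(NA_real_)
      m <- match_edges(results$network$edges, selector$a, selector$b)
      if (!nrow(m)) return(NA_real_)
      if (quantity == "fret_rate") m$rate else m$R
    },
    contact_distance = {
      cm <- results$contacts
      if (is.null(cm) || !nrow(cm)) return(NA_real_)
      hit <- (cm$label_a == selector$a & cm$label_b == selector$b) |
             (cm$label_a == selector$b & cm$label_b == selector$a)
      if (!any(hit)) return(NA_real_)
      cm$min_distance[hit]
    },
    layer_count = {
      ly <- results$layers
      if (is.null(ly) || !selector$layer %in% names(ly$counts))
        return(NA_real_)
      as.numeric(ly$counts[[selector$layer]])
    },
    polar_distance = {
      if (is.null(results$model)) return(NA_real_)
      pc <- polar_contacts(results$model, selector$a, selector$b,
                           d_max = selector$d_max %||% 3.5)
      if (!nrow(pc)) return(NA_real_)
      pc$distance
    },
    stop("unknown expectation quantity: ", quantity, call. = FALSE)
  )
}

#' Compare pipeline results against an expectation set
#'
#' Each expectation is looked up in the freshly computed results; when the
#' selector matches several structural copies (e.g. the two halves of a C2
#' dimer), the copy closest to the expected value is scored — refined
#' models are never exactly symmetric.
#'
#' @param results a result bundle from [run_pipeline()], or any list with
#'   the relevant elements (`census`, `network`, `contacts`, `layers`,
#'   `model`).
#' @param expectations an `expectation_set` from [read_expectations()].
#' @return data.frame: `id`, `quantity`, `expected`, `actual`, `deviation`,
#'   `tolerance`, `pass` (`NA` actual counts as failure).
#' @export
compare_expectations <- function(results, expectations) {
  stopifnot(inherits(expectations, "expectation_set"))
  rows <- lapply(seq_len(nrow(expectations)), function(i) {
    ex <- expectations[i, ]
    vals <- lookup_quantity(ex$quantity, ex$selector[[1L]], results)
    actual <- if (all(is.na(vals))) NA_real_ else
      vals[which.min(abs(vals - ex$expected))]
    dev <- abs(actual - ex$expected)
    data.frame(id = ex$id, quantity = ex$quantity, expected = ex$expected,
               actual = actual, deviation = dev, tolerance = ex$tolerance,
               pass = !is.na(actual) && dev <= ex$tolerance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
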