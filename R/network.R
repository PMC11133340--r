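#' Build the chlorophyll FRET network of an inventory
#'
#' Forms one undirected edge per unordered chlorophyll pair whose Mg–Mg
#' distance is strictly below `params$cutoff`, with the orientation factor,
#' Förster rate and lifetime of each pair. The default selector restricts
#' the nodes to chlorophyll a, matching the convention of computing rates
#' between Chl a molecules only; `all_chl` includes chlorophyll c nodes but
#' applies the single `C` in `params` to every pair, so supply an
#' appropriate value for mixed pairings.
#'
#' @param inventory a `pigment_inventory`.
#' @param params a [fret_params()] object.
#' @param pair_selector `"chl_a_only"` (default) or `"all_chl"`.
#' @return object of class `fret_network`: list with `nodes` (data.frame:
#'   `site_id`, `label`, `subunit`, `kind`, `x`, `y`, `z`), `edges`
#'   (data.frame: `donor`, `acceptor`, `donor_label`, `acceptor_label`, `R`,
#'   `kappa_sq`, `rate`, `lifetime`) and `parameters`.
#' @export
build_network <- function(inventory, params = fret_params(),
                          pair_selector = c("chl_a_only", "all_chl")) {
  stopifnot(inherits(inventory, "pigment_inventory"),
            inherits(params, "fret_params"))
  pair_selector <- match.arg(pair_selector)
  kinds <- if (pair_selector == "chl_a_only") "CHL_A" else CHL_KINDS
  sites <- sites_of_kind(inventory, kinds)
  nodes <- if (length(sites)) data.frame(
    site_id = vapply(sites, `[[`, character(1), "site_id"),
    label = vapply(sites, `[[`, character(1), "pigment_label"),
    subunit = vapply(sites, `[[`, character(1), "subunit_label"),
    kind = vapply(sites, `[[`, character(1), "kind"),
    mg_matrix(sites),
    stringsAsFactors = FALSE
  ) else data.frame(site_id = character(), label = character(),
                    subunit = character(), kind = character(),
                    x = numeric(), y = numeric(), z = numeric(),
                    stringsAsFactors = FALSE)
  if (length(sites)) colnames(nodes)[5:7] <- c("x", "y", "z")
  edges <- empty_edge_table()
  n <- length(sites)
  if (n >= 2L) {
    P <- mg_matrix(sites)
    U <- t(vapply(sites, function(s) qy_dipole(s)$direction, numeric(3)))
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pr[, 1L]; j <- pr[, 2L]
    D <- P[j, , drop = FALSE] - P[i, , drop = FALSE]
    R <- sqrt(rowSums(D * D))
    sel <- R < params$cutoff
    if (any(sel)) {
      i <- i[sel]; j <- j[sel]
      D <- D[sel, , drop = FALSE]; R <- R[sel]
      Rhat <- D / R
      ud_ua <- rowSums(U[i, , drop = FALSE] * U[j, , drop = FALSE])
      ud_r <- rowSums(U[i, , drop = FALSE] * Rhat)
      ua_r <- rowSums(U[j, , drop = FALSE] * Rhat)
      k2 <- (ud_ua - 3 * ud_r * ua_r)^2
      r <- if (params$distance_unit == "nm") R / 10 else R
      rate <- params$C * k2 / (params$n^4 * r^6)
      edges <- data.frame(
        donor = nodes$site_id[i], acceptor = nodes$site_id[j],
        donor_label = paste0(nodes$label[i], "_", nodes$subunit[i]),
        acceptor_label = paste0(nodes$label[j], "_", nodes$subunit[j]),
        R = R, kappa_sq = k2, rate = rate,
        lifetime = ifelse(rate > 0, 1 / rate, NA_real_),
        stringsAsFactors = FALSE
      )
      edges <- edges[order(edges$R), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(
    list(nodes = nodes, edges = edges, parameters = params),
    class = "fret_network"
  )
}

empty_edge_table <- function() {
  data.frame(donor = character(), acceptor = character(),
             donor_label = character(), acceptor_label = character(),
             R = numeric(), kappa_sq = numeric(), rate = numeric(),
             lifetime = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.fret_network <- function(x, ...) {
  cat(sprintf("<fret_network> %d nodes, %d edges (cutoff %g A)\n",
              nrow(x$nodes), nrow(x$edges), x$parameters$cutoff))
  invisible(x)
}

#' Retain only fast transfer edges
#'
#' Keeps edges whose lifetime \eqn{1/k} is strictly below `tau_max`
#' picoseconds (equivalently, rate above `1/tau_max`). Nodes are unchanged,
#' so the filtered object remains comparable with the parent network.
#'
#' @param network a `fret_network`.
#' @param tau_max lifetime threshold in ps (> 0); e.g. 10 and 100 ps select
#'   the fast and the extended transfer networks.
#' @return a `fret_network` with the surviving edges.
#' @export
lifetime_filter <- function(network, tau_max) {
  stopifnot(inherits(network, "fret_network"))
  assert_scalar_number(tau_max, "tau_max", positive = TRUE)
  keep <- network$edges$rate > 1 / tau_max
  network$edges <- network$edges[keep, , drop = FALSE]
  rownames(network$edges) <- NULL
  network
}

#' Export a FRET network
#'
#' `edge_csv` writes the edge list with labels, distances (Å),
#' \eqn{\kappa^2}, rates (ps\eqn{^{-1}}) and lifetimes (ps). `graphml`
#' writes an annotated graph via igraph. `json` writes a lossless
#' serialisation (numbers at 17 significant digits) that
#' [import_network_json()] restores exactly.
#'
#' @param network a `fret_network`.
#' @param path output file path.
#' @param format `"edge_csv"`, `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("edge_csv", "graphml", "json")) {
  stopifnot(inherits(network, "fret_network"))
  format <- match.arg(format)
  if (format == "edge_csv") {
    utils::write.csv(network$edges, path, row.names = FALSE, quote = FALSE)
  } else if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(network$edges)) network$edges else
        data.frame(from = character(), to = character()),
      directed = FALSE,
      vertices = network$nodes[, c("site_id", "label", "subunit", "kind",
                                   "x", "y", "z")]
    )
    igraph::write_graph(g, path, format = "graphml")
  } else {
    payload <- list(
      nodes = network$nodes,
      edges = network$edges,
      parameters = unclass(network$parameters)
    )
    jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Import a FRET network from its JSON export
#' @param path JSON file written by [export_network()] with
#'   `format = "json"`.
#' @return a `fret_network`.
#' @export
import_network_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(p$nodes, stringsAsFactors = FALSE)
  edges <- if (length(p$edges)) as.data.frame(p$edges, stringsAsFactors = FALSE)
           else empty_edge_table()
  if (nrow(edges) && !"lifetime" %in% names(edges))
    edges$lifetime <- ifelse(edges$rate > 0, 1 / edges$rate, NA_real_)
  params <- fret_params(C = p$parameters$C, n = p$parameters$n,
                        cutoff = p$parameters$cutoff,
                        distance_unit = p$parameters$distance_unit)
  structure(list(nodes = nodes, edges = edges, parameters = params),
            class = "fret_network")
}
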