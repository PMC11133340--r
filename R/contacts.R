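# Inter-pigment geometry beyond the FRET rate law: shortest-atom contacts,
# carotenoid-chlorophyll clusters, Mg axial ligands and polar contacts.

# Phytol-tail carbons of chlorophyll a carry bare numeric names (C1..C20);
# ring/ester atoms all carry a letter suffix (C1A, CMA, O1A, ...).
PHYTOL_PATTERN <- "^C([1-9]|1[0-9]|20)$"

site_contact_atoms <- function(site, include_phytol = FALSE) {
  a <- site$atoms
  a <- a[toupper(a$element) != "H", , drop = FALSE]
  if (!include_phytol && site$kind %in% CHL_KINDS)
    a <- a[!grepl(PHYTOL_PATTERN, a$name), , drop = FALSE]
  a
}

#' Shortest atom-atom distance between two pigment sites
#'
#' Minimum Euclidean distance over all retained heavy-atom pairs. By
#' default the phytol-tail carbons of chlorophylls are excluded (the tail
#' is conformationally floppy and conventionally omitted from pigment
#' contact figures); set `include_phytol = TRUE` to keep them.
#'
#' @param site_a,site_b `pigment_site` objects.
#' @param include_phytol keep chlorophyll phytol-tail atoms? Default FALSE.
#' @return object of class `contact_pair`: list with `site_a`, `site_b`
#'   (site ids), `label_a`, `label_b`, `min_distance` (Å), `atom_a`,
#'   `atom_b` (names of the closest pair).
#' @export
min_distance <- function(site_a, site_b, include_phytol = FALSE) {
  aa <- site_contact_atoms(site_a, include_phytol)
  ab <- site_contact_atoms(site_b, include_phytol)
  if (!nrow(aa) || !nrow(ab))
    stop("selection error: no atoms left after filtering for ",
         if (!nrow(aa)) site_a$site_id else site_b$site_id, call. = FALSE)
  pa <- as.matrix(aa[, c("x", "y", "z")])
  pb <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  best <- arrayInd(which.min(d2), dim(d2))
  structure(
    list(site_a = site_a$site_id, site_b = site_b$site_id,
         label_a = site_a$display_label, label_b = site_b$display_label,
         min_distance = sqrt(d2[best]),
         atom_a = aa$name[best[1L]], atom_b = ab$name[best[2L]]),
    class = "contact_pair"
  )
}

#' @export
print.contact_pair <- function(x, ...) {
  cat(sprintf("<contact_pair> %s[%s] -- %s[%s]: %.2f A\n",
              x$label_a, x$atom_a, x$label_b, x$atom_b, x$min_distance))
  invisible(x)
}

#' Map all close cross-kind pigment contacts
#'
#' All unordered pairs with one site in `kinds_a` and one in `kinds_b`
#' whose shortest heavy-atom distance is strictly below `threshold`,
#' sorted by ascending distance. The default 5 Å threshold selects
#' carotenoid-chlorophyll clusters of the kind implicated in energy
#' transfer and triplet quenching.
#'
#' @param inventory a `pigment_inventory`.
#' @param kinds_a,kinds_b character vectors of kinds; defaults pair the
#'   carotenoids against the chlorophylls.
#' @param threshold contact threshold in Å (> 0), default 5.
#' @param include_phytol see [min_distance()].
#' @return data.frame with one row per contact: `site_a`, `site_b`,
#'   `label_a`, `label_b`, `min_distance`, `atom_a`, `atom_b`.
#' @export
contact_map <- function(inventory,
                        kinds_a = c("ALX", "ACAR", "CRO", "MON"),
                        kinds_b = CHL_KINDS,
                        threshold = 5, include_phytol = FALSE) {
  stopifnot(inherits(inventory, "pigment_inventory"))
  assert_scalar_number(threshold, "threshold", positive = TRUE)
  sa <- sites_of_kind(inventory, kinds_a)
  sb <- sites_of_kind(inventory, kinds_b)
  out <- list()
  seen <- character()
  for (s1 in sa) for (s2 in sb) {
    if (identical(s1$site_id, s2$site_id)) next
    key <- paste(sort(c(s1$site_id, s2$site_id)), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    cp <- min_distance(s1, s2, include_phytol)
    if (cp$min_distance < threshold)
      out[[length(out) + 1L]] <- as.data.frame(cp[c(
        "site_a", "site_b", "label_a", "label_b",
        "min_distance", "atom_a", "atom_b")], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(site_a = character(), site_b = character(),
                      label_a = character(), label_b = character(),
                      min_distance = numeric(), atom_a = character(),
                      atom_b = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$min_distance), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect the axial ligand of a chlorophyll's central Mg
#'
#' The fifth (axial) coordination position of the central Mg is assigned to
#' the nearest non-pigment heavy atom — protein side chain or backbone,
#' water, or lipid head group — within `cutoff` Å of the Mg, excluding the
#' chlorophyll's own atoms and any residue mapped to a pigment kind. When
#' nothing qualifies the site is reported as `"unassigned"`.
#'
#' @param chl_site a chlorophyll `pigment_site` with an Mg position.
#' @param model the `structure_model` the site came from.
#' @param cutoff search radius in Å, default 3.5.
#' @param pigment_codes residue names to exclude as ligand donors (default
#'   the chlorophyll + carotenoid codes of [fixture_code_map()]; lipids are
#'   deliberately retained as candidates).
#' @return one-row data.frame: `site`, `label`, `ligand_chain`,
#'   `ligand_resname`, `ligand_resnum`, `ligand_atom`, `distance`
#'   (`NA`/"unassigned" when nothing is within the cutoff).
#' @export
axial_ligand <- function(chl_site, model, cutoff = 3.5,
                         pigment_codes = names(fixture_code_map())[
                           fixture_code_map() %in% PIGMENT_KINDS]) {
  stopifnot(inherits(chl_site, "pigment_site"),
            inherits(model, "structure_model"))
  if (is.null(chl_site$mg_position))
    stop("ligand-geometry error: site ", chl_site$site_id,
         " has no Mg position", call. = FALSE)
  assert_scalar_number(cutoff, "cutoff", positive = TRUE)
  a <- model$atoms
  own <- a$chain_id == chl_site$chain_id &
         a$residue_number == chl_site$residue_number &
         a$residue_name == chl_site$residue_name
  cand <- !own & toupper(a$element) != "H" &
          !(a$residue_name %in% pigment_codes)
  unassigned <- data.frame(
    site = chl_site$site_id, label = chl_site$display_label,
    ligand_chain = NA_character_, ligand_resname = "unassigned",
    ligand_resnum = NA_integer_, ligand_atom = NA_character_,
    distance = NA_real_, stringsAsFactors = FALSE)
  if (!any(cand)) return(unassigned)
  ca <- a[cand, , drop = FALSE]
  d <- sqrt((ca$x - chl_site$mg_position[1])^2 +
            (ca$y - chl_site$mg_position[2])^2 +
            (ca$z - chl_site$mg_position[3])^2)
  i <- which.min(d)
  if (d[i] > cutoff) return(unassigned)
  data.frame(
    site = chl_site$site_id, label = chl_site$display_label,
    ligand_chain = ca$chain_id[i], ligand_resname = ca$residue_name[i],
    ligand_resnum = ca$residue_number[i], ligand_atom = ca$name[i],
    distance = d[i], stringsAsFactors = FALSE)
}

#' Axial ligands for every chlorophyll in an inventory
#' @inheritParams axial_ligand
#' @param inventory a `pigment_inventory`.
#' @return data.frame, one row per chlorophyll (see [axial_ligand()]).
#' @export
axial_ligands <- function(inventory, model, cutoff = 3.5) {
  chl <- sites_of_kind(inventory, CHL_KINDS)
  if (!length(chl)) return(axial_ligand_empty())
  do.call(rbind, lapply(chl, axial_ligand, model = model, cutoff = cutoff))
}

axial_ligand_empty <- function() {
  data.frame(site = character(), label = character(),
             ligand_chain = character(), ligand_resname = character(),
             ligand_resnum = integer(), ligand_atom = character(),
             distance = numeric(), stringsAsFactors = FALSE)
}

# Parse "chain:resnum[:atom]" selection strings into a data.frame.
parse_selection <- function(sel) {
  parts <- strsplit(sel, ":", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop("selection error: expected 'chain:resnum[:atom]', got '",
         sel[bad][1L], "'", call. = FALSE)
  data.frame(
    chain = vapply(parts, `[[`, character(1), 1L),
    resnum = as.integer(vapply(parts, `[[`, character(1), 2L)),
    atom = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]]
                  else NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
}

resolve_selection <- function(model, sel) {
  s <- parse_selection(sel)
  a <- model$atoms
  keep <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(s))) {
    hit <- a$chain_id == s$chain[i] & a$residue_number == s$resnum[i]
    if (!is.na(s$atom[i])) hit <- hit & a$name == s$atom[i]
    keep <- keep | hit
  }
  a[keep, , drop = FALSE]
}

#' Screen polar (hydrogen-bond proxy) contacts between two selections
#'
#' Reports pairs of nitrogen/oxygen atoms, one from each selection, within
#' `d_max` Å. This is a heavy-atom distance-only proxy for hydrogen
#' bonding: atomic models at typical cryo-EM resolution carry no
#' hydrogens, so no angular criterion is applied.
#'
#' @param model a `structure_model`.
#' @param selection_a,selection_b character vectors of
#'   `"chain:resnum[:atom]"` selections.
#' @param d_max distance cutoff in Å, default 3.5.
#' @return data.frame: `chain_a`, `resname_a`, `resnum_a`, `atom_a`,
#'   `chain_b`, `resname_b`, `resnum_b`, `atom_b`, `distance`, sorted by
#'   ascending distance.
#' @export
polar_contacts <- function(model, selection_a, selection_b, d_max = 3.5) {
  stopifnot(inherits(model, "structure_model"))
  assert_scalar_number(d_max, "d_max", positive = TRUE)
  aa <- resolve_selection(model, selection_a)
  ab <- resolve_selection(model, selection_b)
  if (!nrow(aa) || !nrow(ab))
    stop("selection error: selection resolves to zero atoms", call. = FALSE)
  aa <- aa[toupper(aa$element) %in% c("N", "O"), , drop = FALSE]
  ab <- ab[toupper(ab$element) %in% c("N", "O"), , drop = FALSE]
  out <- data.frame(chain_a = character(), resname_a = character(),
                    resnum_a = integer(), atom_a = character(),
                    chain_b = character(), resname_b = character(),
                    resnum_b = integer(), atom_b = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(aa) || !nrow(ab)) return(out)
  pa <- as.matrix(aa[, c("x", "y", "z")])
  pb <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  hits <- which(d2 <= d_max^2, arr.ind = TRUE)
  if (nrow(hits)) {
    out <- data.frame(
      chain_a = aa$chain_id[hits[, 1]], resname_a = aa$residue_name[hits[, 1]],
      resnum_a = aa$residue_number[hits[, 1]], atom_a = aa$name[hits[, 1]],
      chain_b = ab$chain_id[hits[, 2]], resname_b = ab$residue_name[hits[, 2]],
      resnum_b = ab$residue_number[hits[, 2]], atom_b = ab$name[hits[, 2]],
      distance = sqrt(d2[hits]), stringsAsFactors = FALSE)
    same <- out$chain_a == out$chain_b & out$resnum_a == out$resnum_b &
            out$atom_a == out$atom_b
    out <- out[!same, , drop = FALSE]
    out <- out[order(out$distance), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
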