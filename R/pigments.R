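#' Default chemical-component code map
#'
#' Maps chemical-component codes to pigment kinds. Only the chlorophyll codes
#' are universal (`CLA` for chlorophyll a; `KC1`/`KC2` for chlorophylls c1/c2);
#' carotenoid codes vary between depositions and are supplied per accession
#' through a profile file (see [read_profile()]). The thylakoid lipid codes
#' `LMG`, `SQD`, `LHG` are standard and included.
#'
#' @return named character vector, code -> kind.
#' @export
default_code_map <- function() {
  c(CLA = "CHL_A", KC1 = "CHL_C", KC2 = "CHL_C",
    LMG = "LMG", SQD = "SQD", LHG = "LHG")
}

#' Component codes used by the synthetic fixture generator
#'
#' Chlorophylls reuse the real codes so [default_code_map()] applies
#' unchanged; the carotenoid codes (`ALX`, `ACA`, `CRX`, `MND`) are synthetic
#' stand-ins because no universal codes exist for alloxanthin, crocoxanthin
#' and monadoxanthin.
#'
#' @return named character vector, code -> kind.
#' @export
fixture_code_map <- function() {
  c(default_code_map(),
    ALX = "ALX", ACA = "ACAR", CRX = "CRO", MND = "MON")
}

#' Read an accession profile (code map + chain naming map)
#'
#' A profile is a JSON file with a `code_map` object (component code ->
#' kind) and an optional `naming_map` object (chain id -> subunit label,
#' e.g. `"ACPII-3"`, `"CP47"`). Entries whose value starts with `"_"` are
#' treated as documentation placeholders and dropped.
#'
#' @param path path to the JSON profile.
#' @return list with `code_map` and `naming_map` character vectors.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile not found: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- unlist(p$code_map %||% character())
  nm <- unlist(p$naming_map %||% character())
  cm <- cm[!startsWith(cm, "_")]
  bad <- setdiff(unique(cm), ALL_KINDS)
  if (length(bad))
    stop("profile error: unknown kind(s) in code_map: ",
         paste(bad, collapse = ", "), call. = FALSE)
  list(code_map = cm, naming_map = nm)
}

#' Extract pigment and lipid cofactors from a structure model
#'
#' Every residue whose component code appears in `code_map` becomes one
#' `pigment_site`. Chlorophyll sites additionally require a central Mg atom
#' and the NB/ND ring nitrogens (from which the Qy transition dipole is
#' taken); chlorophyll residues missing any of these are skipped with a
#' warning and recorded in the inventory's `skipped` table rather than
#' aborting the extraction.
#'
#' @param model a `structure_model` from [read_structure()].
#' @param code_map named character vector, component code -> kind
#'   (default [default_code_map()]).
#' @param naming_map optional named character vector, chain id -> subunit
#'   label; chains not listed keep their chain id as label.
#' @return an object of class `pigment_inventory`: list with `sites` (list of
#'   `pigment_site`), `naming_map` and `skipped` (data.frame).
#' @export
extract_pigments <- function(model, code_map = default_code_map(),
                             naming_map = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (!length(code_map)) stop("code_map must be non-empty", call. = FALSE)
  atoms <- model$atoms
  sel <- atoms$residue_name %in% names(code_map)
  sites <- list()
  skipped <- list()
  if (any(sel)) {
    sub <- atoms[sel, , drop = FALSE]
    key <- paste(sub$chain_id, sub$residue_number, sub$residue_name, sep = "\r")
    for (k in unique(key)) {
      res_atoms <- sub[key == k, , drop = FALSE]
      chain <- res_atoms$chain_id[1L]
      resno <- res_atoms$residue_number[1L]
      resnm <- res_atoms$residue_name[1L]
      kind <- unname(code_map[[resnm]])
      mg <- NULL
      if (kind %in% CHL_KINDS) {
        img <- which(toupper(res_atoms$element) == "MG" |
                     res_atoms$name == "MG")[1L]
        have_nb <- "NB" %in% res_atoms$name
        have_nd <- "ND" %in% res_atoms$name
        if (is.na(img) || !have_nb || !have_nd) {
          what <- c(if (is.na(img)) "Mg", if (!have_nb) "NB",
                    if (!have_nd) "ND")
          skipped[[length(skipped) + 1L]] <- data.frame(
            chain_id = chain, residue_number = resno, residue_name = resnm,
            missing = paste(what, collapse = "+"), stringsAsFactors = FALSE)
          next
        }
        mg <- as.numeric(res_atoms[img, c("x", "y", "z")])
      }
      subunit <- if (!is.null(naming_map) && chain %in% names(naming_map))
        unname(naming_map[[chain]]) else chain
      prefix <- kind_label_prefix[kind]
      label <- if (!is.na(prefix)) paste0(prefix, resno)
               else paste0(resnm, resno)
      sites[[length(sites) + 1L]] <- structure(
        list(
          kind = kind, chain_id = chain, residue_number = resno,
          residue_name = resnm, subunit_label = subunit,
          pigment_label = label,
          display_label = paste0(label, "_", subunit),
          site_id = paste(chain, resnm, resno, sep = ":"),
          atoms = res_atoms, mg_position = mg
        ),
        class = "pigment_site"
      )
    }
  }
  if (length(skipped)) {
    skipped <- do.call(rbind, skipped)
    warning(sprintf("skipped %d chlorophyll residue(s) missing Mg/NB/ND (e.g. %s %s%d)",
                    nrow(skipped), skipped$chain_id[1L], skipped$residue_name[1L],
                    skipped$residue_number[1L]), call. = FALSE)
  } else {
    skipped <- data.frame(chain_id = character(), residue_number = integer(),
                          residue_name = character(), missing = character(),
                          stringsAsFactors = FALSE)
  }
  structure(
    list(sites = sites, naming_map = naming_map, skipped = skipped),
    class = "pigment_inventory"
  )
}

#' @export
print.pigment_inventory <- function(x, ...) {
  kinds <- vapply(x$sites, `[[`, character(1), "kind")
  cat(sprintf("<pigment_inventory> %d sites", length(x$sites)))
  if (length(kinds)) {
    tab <- table(kinds)
    cat(": ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

site_kinds <- function(inventory)
  vapply(inventory$sites, `[[`, character(1), "kind")

site_ids <- function(inventory)
  vapply(inventory$sites, `[[`, character(1), "site_id")

#' Select sites of given kinds from an inventory
#' @param inventory a `pigment_inventory`.
#' @param kinds character vector of kinds (see `default_code_map()` values).
#' @return list of `pigment_site`.
#' @export
sites_of_kind <- function(inventory, kinds) {
  inventory$sites[site_kinds(inventory) %in% kinds]
}

# n x 3 matrix of Mg positions for chlorophyll sites, rownames = site ids
mg_matrix <- function(sites) {
  if (!length(sites)) return(matrix(numeric(), 0L, 3L))
  m <- t(vapply(sites, function(s) s$mg_position, numeric(3)))
  rownames(m) <- vapply(sites, `[[`, character(1), "site_id")
  m
}

#' Tabulate the pigment and lipid census of an inventory
#'
#' Counts sites per kind over the full kind vocabulary and totals them
#' separately over pigments (chlorophylls + carotenoids) and lipids. The
#' per-kind counts always partition the extracted sites.
#'
#' @param inventory a `pigment_inventory`.
#' @return object of class `census_table`: list with `counts` (named integer
#'   vector over all kinds), `total_pigments`, `total_lipids`.
#' @export
pigment_census <- function(inventory) {
  stopifnot(inherits(inventory, "pigment_inventory"))
  kinds <- factor(site_kinds(inventory), levels = ALL_KINDS)
  counts <- table(kinds)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(
      counts = counts,
      total_pigments = sum(counts[PIGMENT_KINDS]),
      total_lipids = sum(counts[LIPID_KINDS])
    ),
    class = "census_table"
  )
}

#' @export
print.census_table <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat("<census_table>\n")
  if (length(nz))
    for (k in names(nz)) cat(sprintf("  %-6s %d\n", k, nz[[k]]))
  cat(sprintf("  pigments %d, lipids %d\n", x$total_pigments, x$total_lipids))
  invisible(x)
}

#' @export
as.data.frame.census_table <- function(x, ...) {
  data.frame(kind = names(x$counts), count = unname(x$counts),
             stringsAsFactors = FALSE)
}

#' Write a census table to CSV or JSON
#' @param census a `census_table`.
#' @param path output file; format decided by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  stopifnot(inherits(census, "census_table"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(counts = as.list(census$counts),
           total_pigments = census$total_pigments,
           total_lipids = census$total_lipids),
      path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.csv(as.data.frame(census), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
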