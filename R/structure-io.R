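#' Read a macromolecular structure file
#'
#' Parses the atomic coordinates of an mmCIF (PDBx `_atom_site` loop) or PDB
#' (fixed-column `ATOM`/`HETATM` records) file into a `structure_model`:
#' a flat atom table plus metadata. Alternate locations are resolved
#' deterministically per residue: the conformer with the highest mean
#' occupancy is kept, ties broken by the lexicographically smallest altloc
#' identifier. Atoms without an altloc are always kept.
#'
#' @param path path to the structure file.
#' @param format `"mmcif"`, `"pdb"` or `"auto"` (default; decided from the
#'   file extension, falling back to content sniffing).
#' @return an object of class `structure_model`: a list with `atoms`
#'   (data.frame with columns `name`, `element`, `x`, `y`, `z`, `chain_id`,
#'   `residue_name`, `residue_number`, `altloc`, `occupancy`, `group`) and
#'   `metadata` (list with `title`, `accession`, `path`, `format`).
#' @examples
#' spec <- fixture_spec(list(
#'   chl_placement("A", 601, c(0, 0, 0), c(0, 0, 1))))
#' f <- tempfile(fileext = ".cif")
#' make_fixture(spec, f)
#' model <- read_structure(f)
#' nrow(model$atoms)
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("parse error: file is empty: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  lines <- readLines(path, warn = FALSE)
  atoms <- switch(format,
    mmcif = parse_mmcif_atoms(lines, path),
    pdb   = parse_pdb_atoms(lines, path)
  )
  if (nrow(atoms) == 0L)
    stop("parse error: no atom records found in ", path, call. = FALSE)
  atoms <- resolve_altlocs(atoms)
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad))
    stop("parse error: non-finite coordinates at atom row ", which(bad)[1L],
         " of ", path, call. = FALSE)
  structure(
    list(
      atoms = atoms,
      metadata = list(
        title = extract_title(lines, format),
        accession = NA_character_,
        path = path,
        format = format
      )
    ),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d chains [%s]\n",
              nrow(x$atoms), length(unique(x$atoms$chain_id)),
              x$metadata$format))
  invisible(x)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^data_", head_lines)) || any(grepl("^_atom_site\\.", head_lines)))
    return("mmcif")
  if (any(grepl("^(ATOM|HETATM|HEADER|CRYST1)", head_lines)))
    return("pdb")
  stop("format error: cannot determine format of ", path, call. = FALSE)
}

extract_title <- function(lines, format) {
  if (format == "pdb") {
    t <- lines[startsWith(lines, "TITLE")]
    if (length(t)) return(trimws(paste(substring(t, 11), collapse = " ")))
  } else {
    i <- grep("^_struct\\.title", lines)
    if (length(i)) return(trimws(gsub("^_struct\\.title\\s*", "", lines[i[1L]])))
  }
  NA_character_
}

## ---- PDB ------------------------------------------------------------------

parse_pdb_atoms <- function(lines, path) {
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) return(empty_atom_table())
  num <- function(s, what, line_ids) {
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v) & nzchar(trimws(s))
    if (any(bad))
      stop(sprintf("parse error: bad %s field in %s at record %d", what,
                   path, line_ids[which(bad)[1L]]), call. = FALSE)
    v
  }
  field <- function(from, to) trimws(substring(rec, from, to))
  ids <- seq_along(rec)
  occ <- num(field(55, 60), "occupancy", ids)
  occ[is.na(occ)] <- 1
  el <- field(77, 78)
  name <- field(13, 16)
  # infer element from atom name when column 77-78 is absent
  miss <- !nzchar(el)
  el[miss] <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name[miss]))
  el <- ifelse(nchar(el) > 1,
               paste0(substr(el, 1, 1), tolower(substr(el, 2, 2))), el)
  data.frame(
    name = name,
    element = el,
    x = num(field(31, 38), "x", ids),
    y = num(field(39, 46), "y", ids),
    z = num(field(47, 54), "z", ids),
    chain_id = field(22, 22),
    residue_name = field(18, 20),
    residue_number = as.integer(num(field(23, 26), "residue number", ids)),
    altloc = field(17, 17),
    occupancy = pmin(pmax(occ, 0), 1),
    group = trimws(substring(rec, 1, 6)),
    stringsAsFactors = FALSE
  )
}

## ---- mmCIF ----------------------------------------------------------------

# Tokenise one mmCIF data line, honouring single/double quoted values.
cif_tokens <- function(line) {
  out <- character()
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch %in% c("'", '"')) {
      j <- i + 1L
      repeat {
        k <- regexpr(ch, substr(line, j, n), fixed = TRUE)
        if (k < 0) { j <- n + 1L; break }
        j <- j + k - 1L
        nxt <- substr(line, j + 1L, j + 1L)
        if (nxt == "" || nxt %in% c(" ", "\t")) break
        j <- j + 1L
      }
      out <- c(out, substr(line, i + 1L, min(j, n + 1L) - 1L))
      i <- j + 1L
    } else {
      m <- regexpr("[ \t]", substr(line, i, n))
      j <- if (m < 0) n + 1L else i + m - 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

parse_mmcif_atoms <- function(lines, path) {
  tag_idx <- grep("^_atom_site\\.", lines)
  if (!length(tag_idx)) return(empty_atom_table())
  first <- tag_idx[1L]
  run <- tag_idx[cumsum(c(1L, diff(tag_idx)) != 1L) == 0L]
  tags <- sub("^_atom_site\\.", "", trimws(lines[run]))
  body_start <- run[length(run)] + 1L
  toks <- character(); row_end <- body_start - 1L
  for (i in body_start:length(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*(#|loop_|_[A-Za-z]|data_)", ln) || grepl("^;", ln)) break
    if (!nzchar(trimws(ln))) next
    toks <- c(toks, cif_tokens(ln))
    row_end <- i
  }
  if (!length(toks)) return(empty_atom_table())
  if (length(toks) %% length(tags) != 0L)
    stop(sprintf(
      "parse error: _atom_site loop in %s has %d values for %d columns (near line %d)",
      path, length(toks), length(tags), row_end), call. = FALSE)
  m <- matrix(toks, ncol = length(tags), byrow = TRUE)
  colnames(m) <- tags
  col <- function(auth, label, default = NA_character_) {
    if (auth %in% tags) m[, auth]
    else if (label %in% tags) m[, label]
    else rep(default, nrow(m))
  }
  undot <- function(v, default = "") { v[v %in% c(".", "?")] <- default; v }
  occ <- suppressWarnings(as.numeric(undot(col("occupancy", "occupancy"), "1")))
  occ[is.na(occ)] <- 1
  data.frame(
    name = undot(col("auth_atom_id", "label_atom_id")),
    element = undot(col("type_symbol", "type_symbol")),
    x = as.numeric(col("Cartn_x", "Cartn_x")),
    y = as.numeric(col("Cartn_y", "Cartn_y")),
    z = as.numeric(col("Cartn_z", "Cartn_z")),
    chain_id = undot(col("auth_asym_id", "label_asym_id")),
    residue_name = undot(col("auth_comp_id", "label_comp_id")),
    residue_number = as.integer(suppressWarnings(
      as.numeric(undot(col("auth_seq_id", "label_seq_id"), "0")))),
    altloc = undot(col("label_alt_id", "label_alt_id")),
    occupancy = pmin(pmax(occ, 0), 1),
    group = undot(col("group_PDB", "group_PDB"), "HETATM"),
    stringsAsFactors = FALSE
  )
}

empty_atom_table <- function() {
  data.frame(
    name = character(), element = character(),
    x = numeric(), y = numeric(), z = numeric(),
    chain_id = character(), residue_name = character(),
    residue_number = integer(), altloc = character(),
    occupancy = numeric(), group = character(),
    stringsAsFactors = FALSE
  )
}

# Per-residue conformer selection: among non-blank altlocs of one residue,
# keep the altloc with the highest mean occupancy (tie -> smallest id).
resolve_altlocs <- function(atoms) {
  if (!any(nzchar(atoms$altloc))) return(atoms)
  res_key <- paste(atoms$chain_id, atoms$residue_number, atoms$residue_name,
                   sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (key in unique(res_key[nzchar(atoms$altloc)])) {
    idx <- which(res_key == key & nzchar(atoms$altloc))
    alts <- atoms$altloc[idx]
    if (length(unique(alts)) < 2L) next
    mean_occ <- tapply(atoms$occupancy[idx], alts, mean)
    best <- names(mean_occ)[order(-mean_occ, names(mean_occ))][1L]
    keep[idx[alts != best]] <- FALSE
  }
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
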