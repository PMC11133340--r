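#' Configuration for the end-to-end analysis pipeline
#'
#' @param structure path to the structure file (mmCIF/PDB).
#' @param profile optional path to a JSON profile ([read_profile()]); when
#'   absent, [default_code_map()] applies and chains label themselves.
#' @param params a [fret_params()] object.
#' @param taus lifetime thresholds (ps) for the filtered networks; default
#'   `c(10, 100)`, the fast and the extended transfer networks.
#' @param contact_threshold carotenoid–chlorophyll contact threshold, Å.
#' @param ligand_cutoff Mg axial-ligand search radius, Å.
#' @param out_dir output directory (created if missing).
#' @param expectations optional path to an expectation JSON
#'   ([read_expectations()]).
#' @param stromal_direction optional 3-vector orienting the layer labels
#'   (see [classify_layers()]).
#' @return object of class `run_config`.
#' @export
run_config <- function(structure, profile = NULL, params = fret_params(),
                       taus = c(10, 100), contact_threshold = 5,
                       ligand_cutoff = 3.5, out_dir = tempfile("eetnet_run_"),
                       expectations = NULL, stromal_direction = NULL) {
  if (!file.exists(structure))
    stop("validation error: structure file not found: ", structure,
         call. = FALSE)
  if (!is.null(profile) && !file.exists(profile))
    stop("validation error: profile not found: ", profile, call. = FALSE)
  if (!length(taus) || any(!is.finite(taus)) || any(taus <= 0))
    stop("validation error: taus must be a non-empty vector of positive lifetimes",
         call. = FALSE)
  assert_scalar_number(contact_threshold, "contact_threshold", positive = TRUE)
  assert_scalar_number(ligand_cutoff, "ligand_cutoff", positive = TRUE)
  if (!is.null(expectations) && !file.exists(expectations))
    stop("validation error: expectations file not found: ", expectations,
         call. = FALSE)
  structure(
    list(structure = structure, profile = profile, params = params,
         taus = as.numeric(taus), contact_threshold = contact_threshold,
         ligand_cutoff = ligand_cutoff, out_dir = out_dir,
         expectations = expectations, stromal_direction = stromal_direction),
    class = "run_config"
  )
}

#' Run the full census / FRET / contacts / layers pipeline
#'
#' Stages: read structure -> extract pigments -> census -> FRET network
#' (full + one lifetime-filtered network per `tau`) -> carotenoid contact
#' map -> axial-ligand table -> layer classification -> optional comparison
#' against an expectation set. Every stage's table is written under
#' `config$out_dir`; the pipeline is fully deterministic (no unseeded
#' randomness anywhere). A stage failure is re-raised with the stage name.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages? Default TRUE.
#' @return (invisibly) object of class `eet_report`: list with `model`,
#'   `inventory`, `census`, `network`, `filtered` (named by tau),
#'   `contacts`, `ligands`, `layers`, `comparison` (or NULL), `passed`
#'   (logical or NA), `out_dir`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  prof <- if (!is.null(config$profile)) stage("profile", read_profile(config$profile))
          else list(code_map = default_code_map(), naming_map = NULL)

  say("reading %s", config$structure)
  model <- stage("read_structure", read_structure(config$structure))
  inventory <- stage("extract_pigments",
    extract_pigments(model, code_map = prof$code_map,
                     naming_map = prof$naming_map))
  census <- stage("census", pigment_census(inventory))
  write_census(census, file.path(config$out_dir, "census.csv"))
  write_census(census, file.path(config$out_dir, "census.json"))

  say("building FRET network (%d chlorophyll-a sites)",
      sum(site_kinds(inventory) == "CHL_A"))
  network <- stage("build_network", build_network(inventory, config$params))
  export_network(network, file.path(config$out_dir, "network_edges.csv"),
                 "edge_csv")
  export_network(network, file.path(config$out_dir, "network.graphml"),
                 "graphml")
  export_network(network, file.path(config$out_dir, "network.json"), "json")
  filtered <- list()
  for (tau in config$taus) {
    f <- stage("lifetime_filter", lifetime_filter(network, tau))
    filtered[[sprintf("tau_%g", tau)]] <- f
    export_network(f, file.path(config$out_dir,
                                sprintf("network_tau%g.csv", tau)),
                   "edge_csv")
  }

  contacts <- stage("contact_map",
    contact_map(inventory, threshold = config$contact_threshold))
  utils::write.csv(contacts, file.path(config$out_dir, "contacts.csv"),
                   row.names = FALSE, quote = FALSE)
  ligands <- stage("axial_ligands",
    axial_ligands(inventory, model, cutoff = config$ligand_cutoff))
  utils::write.csv(ligands, file.path(config$out_dir, "ligands.csv"),
                   row.names = FALSE, quote = FALSE)

  layers <- NULL
  if (length(sites_of_kind(inventory, CHL_KINDS)) >= 2L) {
    layers <- stage("classify_layers", suppressWarnings(
      classify_layers(inventory,
                      stromal_direction = config$stromal_direction)))
    utils::write.csv(layers$table, file.path(config$out_dir, "layers.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  comparison <- NULL; passed <- NA
  results <- list(model = model, inventory = inventory, census = census,
                  network = network, filtered = filtered,
                  contacts = contacts, ligands = ligands, layers = layers)
  if (!is.null(config$expectations)) {
    ex <- stage("expectations", read_expectations(config$expectations))
    comparison <- stage("compare", compare_expectations(results, ex))
    utils::write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
                     row.names = FALSE, quote = FALSE)
    passed <- all(comparison$pass)
    say("expectations: %d/%d pass", sum(comparison$pass), nrow(comparison))
  }
  report <- structure(
    c(results, list(comparison = comparison, passed = passed,
                    out_dir = config$out_dir)),
    class = "eet_report")
  invisible(report)
}

#' @export
print.eet_report <- function(x, ...) {
  cat("<eet_report>\n")
  print(x$census)
  print(x$network)
  for (nm in names(x$filtered))
    cat(sprintf("  %s: %d edges\n", nm, nrow(x$filtered[[nm]]$edges)))
  cat(sprintf("  contacts: %d, ligands assigned: %d/%d\n",
              nrow(x$contacts),
              sum(x$ligands$ligand_resname != "unassigned"),
              nrow(x$ligands)))
  if (!is.null(x$layers)) print(x$layers)
  if (!is.null(x$comparison))
    cat(sprintf("  expectations: %d/%d pass\n",
                sum(x$comparison$pass), nrow(x$comparison)))
  cat("  outputs:", x$out_dir, "\n")
  invisible(x)
}
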