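# Shared builders for synthetic fixtures and independent oracles.

dipole <- function(origin, direction) {
  structure(list(site_id = "synthetic", origin = as.numeric(origin),
                 direction = direction / sqrt(sum(direction^2))),
            class = "transition_dipole")
}

# Random chlorophyll-a placements in a box, pairwise separation >= min_sep.
random_chl_spec <- function(n, seed, box = 60, min_sep = 4) {
  set.seed(seed)
  pts <- matrix(numeric(), 0, 3)
  while (nrow(pts) < n) {
    p <- stats::runif(3, 0, box)
    if (!nrow(pts) || min(sqrt(rowSums(sweep(pts, 2, p)^2))) >= min_sep)
      pts <- rbind(pts, p)
  }
  dirs <- matrix(stats::rnorm(3 * n), ncol = 3)
  placements <- lapply(seq_len(n), function(i)
    chl_placement("A", 600 + i, pts[i, ], dirs[i, ] / sqrt(sum(dirs[i, ]^2))))
  fixture_spec(placements, noise_sigma = 0, seed = seed)
}

# Brute-force all-pairs network oracle built from the scalar primitives,
# independent of build_network's vectorised pair machinery.
brute_force_edges <- function(inventory, params = fret_params()) {
  sites <- sites_of_kind(inventory, "CHL_A")
  out <- list()
  if (length(sites) >= 2) {
    for (i in seq_len(length(sites) - 1)) for (j in (i + 1):length(sites)) {
      di <- qy_dipole(sites[[i]]); dj <- qy_dipole(sites[[j]])
      R <- sqrt(sum((dj$origin - di$origin)^2))
      if (R >= params$cutoff) next
      out[[length(out) + 1]] <- data.frame(
        donor = sites[[i]]$site_id, acceptor = sites[[j]]$site_id,
        R = R, kappa_sq = orientation_factor(di, dj),
        rate = fret_rate(di, dj, params), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(donor = character(), acceptor = character(),
                      R = numeric(), kappa_sq = numeric(), rate = numeric()))
  do.call(rbind, out)
}

# Canonical unordered pair keys for edge-set comparison.
pair_keys <- function(df) {
  if (!nrow(df)) return(character())
  sort(paste(pmin(df$donor, df$acceptor), pmax(df$donor, df$acceptor)))
}

site_ids_of <- function(inv) vapply(inv$sites, `[[`, character(1), "site_id")

site_kinds <- function(inv) vapply(inv$sites, `[[`, character(1), "kind")

inventory_from_spec <- function(spec, format = "mmcif") {
  path <- tempfile(fileext = if (format == "mmcif") ".cif" else ".pdb")
  make_fixture(spec, path, format = format)
  extract_pigments(read_structure(path), fixture_code_map())
}
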