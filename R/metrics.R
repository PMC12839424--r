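#' Perturbation metric configuration
#'
#' Defaults follow the analysis conventions: a local window of five residues
#' on each side of the mutation site, an 8 Angstrom Cα neighborhood, and a
#' 3 Angstrom flag line on |delta-D|.
#'
#' @param flank Residues on each side of the site in the local window.
#' @param neighbor_cutoff Cα-Cα distance (Angstrom) defining neighbors.
#' @param flag_threshold |delta-D| at or above which a record is flagged.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(flank = 5L, neighbor_cutoff = 8.0, flag_threshold = 3.0) {
  if (flank < 0 || neighbor_cutoff <= 0 || flag_threshold <= 0)
    vs_abort("flank must be >= 0 and cutoffs positive", "varstruct_domain")
  structure(list(flank = as.integer(flank),
                 neighbor_cutoff = neighbor_cutoff,
                 flag_threshold = flag_threshold),
            class = "metric_config")
}

#' Mutation-site specification
#'
#' A substitution site lives at a paired WT residue; an insertion site lives
#' at a mutant-only (inserted) residue. For insertions the WT-side reference
#' point is the residue immediately preceding the insertion (the inserted
#' residue has no WT counterpart) — an explicit convention echoed in output
#' metadata.
#'
#' @param kind `"substitution"` or `"insertion"`.
#' @param wt_index WT residue index (substitutions).
#' @param mut_index Mutant residue index (insertions; resolved from the map
#'   for substitutions when omitted).
#' @param label Display label, e.g. the effect notation.
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(kind = c("substitution", "insertion"), wt_index = NA,
                      mut_index = NA, label = "") {
  kind <- match.arg(kind)
  if (kind == "substitution" && is.na(wt_index))
    vs_abort("substitution sites need wt_index", "varstruct_domain")
  if (kind == "insertion" && is.na(mut_index))
    vs_abort("insertion sites need mut_index", "varstruct_domain")
  structure(list(kind = kind, wt_index = as.integer(wt_index),
                 mut_index = as.integer(mut_index),
                 label = if (nzchar(label)) label else
                   sprintf("%s%d", substr(kind, 1, 3),
                           if (kind == "substitution") wt_index else mut_index)),
            class = "site_spec")
}

# WT-side and mutant-side residue indices anchoring a site.
resolve_site <- function(site, map) {
  if (site$kind == "substitution") {
    mi <- if (is.na(site$mut_index)) mut_partner(map, site$wt_index) else site$mut_index
    if (is.na(mi))
      vs_abort(sprintf("substitution site WT %d is unpaired in the map",
                       site$wt_index), "varstruct_domain")
    list(wt = site$wt_index, mut = mi)
  } else {
    if (!site$mut_index %in% map$mut_only)
      vs_abort(sprintf("insertion site %d is not a mutant-only residue",
                       site$mut_index), "varstruct_domain")
    prev <- map$pairs[map$pairs[, 2] < site$mut_index, , drop = FALSE]
    if (nrow(prev) == 0L)
      vs_abort("insertion before the first paired residue has no WT anchor",
               "varstruct_domain")
    list(wt = prev[nrow(prev), 1], mut = site$mut_index)
  }
}

#' Local residue window around a mutation site
#'
#' Window of `flank` residues on each side of the site, clipped to the
#' model: WT indices `[i - flank, i + flank]` intersected with `[1, n]`.
#' Insertion sites are centered on the inserted mutant residue and mapped
#' to WT through the correspondence (the inserted residue itself has no WT
#' member).
#'
#' @param model The WT [structure_model()].
#' @param site A [site_spec()].
#' @param flank Residues per side.
#' @param map A [correspondence_map()] (required for insertion sites).
#' @param mut The mutant model (required for insertion sites).
#' @return Integer vector of WT residue indices.
#' @export
local_window <- function(model, site, flank, map = NULL, mut = NULL) {
  if (site$kind == "substitution") {
    i <- site$wt_index
    seq.int(max(1L, i - flank), min(n_residues(model), i + flank))
  } else {
    stopifnot(!is.null(map), !is.null(mut))
    mw <- seq.int(max(1L, site$mut_index - flank),
                  min(n_residues(mut), site$mut_index + flank))
    sort(map$pairs[map$pairs[, 2] %in% mw, 1])
  }
}

#' Local-window RMSD at a mutation site
#'
#' RMSD over the paired Cα atoms of the local window, measured under the
#' *global* superposition transform — no local re-fitting. Measuring in the
#' global frame is what lets a locally displaced segment register its full
#' excursion (local re-fitting would hide it).
#'
#' @param wt,mut [structure_model()] objects.
#' @param map A [correspondence_map()].
#' @param super A `superposition_result` from [superpose()].
#' @param site A [site_spec()].
#' @param cfg A [metric_config()].
#' @return List: `site` (label), `window` (WT index range), `n_pairs`,
#'   `value` (Angstrom).
#' @export
local_rmsd <- function(wt, mut, map, super, site, cfg = metric_config()) {
  win <- local_window(wt, site, cfg$flank, map = map, mut = mut)
  rows <- which(map$pairs[, 1] %in% win)
  if (!length(rows))
    vs_abort(sprintf("no paired residues in the window of site %s", site$label),
             "varstruct_empty_window")
  P <- ca_coords(wt)[map$pairs[rows, 1], , drop = FALSE]
  Q <- apply_transform(super$transform,
                       ca_coords(mut)[map$pairs[rows, 2], , drop = FALSE])
  list(site = site$label,
       window = sprintf("%d-%d", min(win), max(win)),
       n_pairs = length(rows),
       value = sqrt(mean(rowSums((Q - P)^2))))
}

#' Neighbor residues of a mutation site
#'
#' All residues whose Cα lies within `neighbor_cutoff` of the site Cα,
#' excluding the site itself, sorted by index. Substitution sites are probed
#' in the WT structure (the pre-mutation reference); insertion sites are
#' probed in the mutant around the inserted residue and the hits mapped back
#' to WT indices (unmatched hits dropped).
#'
#' @param wt The WT [structure_model()].
#' @param site A [site_spec()].
#' @param cfg A [metric_config()].
#' @param mut,map Mutant model and [correspondence_map()] (insertion sites).
#' @return Sorted integer vector of WT residue indices.
#' @export
find_neighbors <- function(wt, site, cfg = metric_config(), mut = NULL,
                           map = NULL) {
  if (site$kind == "substitution") {
    xyz <- ca_coords(wt)
    i <- site$wt_index
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    sort(setdiff(which(d <= cfg$neighbor_cutoff), i))
  } else {
    stopifnot(!is.null(mut), !is.null(map))
    xyz <- ca_coords(mut)
    i <- site$mut_index
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    hits <- setdiff(which(d <= cfg$neighbor_cutoff), i)
    sort(map$pairs[map$pairs[, 2] %in% hits, 1])
  }
}

#' Neighbor-distance change (delta-D) records for one site
#'
#' For each neighbor j: `d_wt` is the WT Cα-Cα distance from the site to j,
#' `d_mut` the mutant distance between their counterparts, and
#' `delta_d = d_mut - d_wt` (signed). Internal distances make the statistic
#' superposition-independent. Records are flagged when
#' `|delta_d| >= flag_threshold`. Neighbors without a mutant counterpart are
#' skipped with a warning.
#'
#' @param wt,mut [structure_model()] objects.
#' @param map A [correspondence_map()].
#' @param site A [site_spec()].
#' @param neighbors WT residue indices (e.g. from [find_neighbors()]).
#' @param cfg A [metric_config()].
#' @return Data frame: `site`, `neighbor`, `d_wt`, `d_mut`, `delta_d`,
#'   `flagged`.
#' @export
compute_delta_d <- function(wt, mut, map, site, neighbors,
                            cfg = metric_config()) {
  anchor <- resolve_site(site, map)
  wt_xyz <- ca_coords(wt); mut_xyz <- ca_coords(mut)
  site_wt <- wt_xyz[anchor$wt, ]; site_mut <- mut_xyz[anchor$mut, ]
  rows <- lapply(sort(neighbors), function(j) {
    jm <- mut_partner(map, j)
    if (is.na(jm)) {
      vs_warn(sprintf("neighbor %d has no mutant counterpart; record skipped", j),
              "varstruct_unmatched_neighbor")
      return(NULL)
    }
    d_wt <- sqrt(sum((site_wt - wt_xyz[j, ])^2))
    d_mut <- sqrt(sum((site_mut - mut_xyz[jm, ])^2))
    data.frame(site = site$label, neighbor = j, d_wt = d_wt, d_mut = d_mut,
               delta_d = d_mut - d_wt,
               flagged = abs(d_mut - d_wt) >= cfg$flag_threshold)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(site = character(), neighbor = integer(),
                      d_wt = numeric(), d_mut = numeric(),
                      delta_d = numeric(), flagged = logical())
  out
}

#' Full perturbation report
#'
#' Assembles the three perturbation statistics for a set of mutation sites:
#' one global superposition block, one local-RMSD row per site, and one
#' delta-D row per (site, neighbor), in deterministic order (sites by index,
#' neighbors by index). Per-site failures (e.g. an empty window) are
#' collected and reported without aborting the remaining sites.
#'
#' @param wt,mut [structure_model()] objects.
#' @param map A [correspondence_map()].
#' @param sites List of [site_spec()] objects.
#' @param cfg A [metric_config()].
#' @param cycles,reject_cutoff,fit_subset Passed to [superpose()].
#' @return An object of class `perturbation_report`: `global` (RMSD block),
#'   `local` (data frame), `delta_d` (data frame), `failures` (character),
#'   `config`.
#' @export
perturbation_report <- function(wt, mut, map, sites, cfg = metric_config(),
                                cycles = 0L, reject_cutoff = 2.0,
                                fit_subset = NULL) {
  super <- superpose(wt, mut, map, cycles = cycles,
                     reject_cutoff = reject_cutoff, fit_subset = fit_subset)
  ord <- order(vapply(sites, function(s)
    if (s$kind == "substitution") s$wt_index else s$mut_index, 1L))
  local_rows <- list(); dd_rows <- list(); failures <- character(0)
  for (s in sites[ord]) {
    res <- tryCatch({
      lr <- local_rmsd(wt, mut, map, super, s, cfg)
      nb <- find_neighbors(wt, s, cfg, mut = mut, map = map)
      dd <- compute_delta_d(wt, mut, map, s, nb, cfg)
      list(lr = lr, dd = dd)
    }, varstruct_error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", s$label, conditionMessage(res)))
      next
    }
    local_rows[[length(local_rows) + 1L]] <-
      data.frame(site = res$lr$site, window = res$lr$window,
                 n_pairs = res$lr$n_pairs, rmsd = res$lr$value)
    dd_rows[[length(dd_rows) + 1L]] <- res$dd
  }
  structure(list(
    global = list(rmsd_all = super$rmsd_all,
                  rmsd_retained = super$rmsd_retained,
                  n_pairs = super$n_pairs,
                  n_retained = length(super$retained),
                  cycles_run = super$cycles_run),
    local = do.call(rbind, c(local_rows, list(make.row.names = FALSE))),
    delta_d = do.call(rbind, c(dd_rows, list(make.row.names = FALSE))),
    failures = failures,
    config = cfg,
    superposition = super),
    class = "perturbation_report")
}

#' @export
print.perturbation_report <- function(x, ...) {
  cat(sprintf("<perturbation_report> global RMSD %.3f A (all) / %.3f A (retained)\n",
              x$global$rmsd_all, x$global$rmsd_retained))
  cat(sprintf("  %d local-RMSD site(s), %d delta-D record(s), %d flagged\n",
              if (is.null(x$local)) 0L else nrow(x$local),
              if (is.null(x$delta_d)) 0L else nrow(x$delta_d),
              if (is.null(x$delta_d)) 0L else sum(x$delta_d$flagged)))
  if (length(x$failures))
    cat("  failures:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}
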