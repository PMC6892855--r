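# Synthetic multi-group ordinal symptom cohorts with a known Ising
# dependence structure between symptom domains.

# deterministic child seeds: one master seed, one child per (stage, group)
derive_seed <- function(master, stage, group = 0L) {
  s <- (as.numeric(master) + 1000003 * stage + 7919 * group) %% 2147483629
  as.integer(s) + 1L
}

#' Specify a synthetic symptom cohort
#'
#' Describes K severity groups of individuals. For each group, latent binary
#' domain states are drawn from that group's ground-truth Ising network;
#' observed ordinal item scores (0/1/2, the usual broadband-questionnaire
#' coding: not true / somewhat or sometimes true / very or often true) are
#' then emitted per item with a mean that increases both with the latent
#' domain state and with the group's severity offset. Severity offsets are
#' required to be non-decreasing in group index, producing the group-ordered
#' severity gradient (and the floor effects in mild groups) that the
#' prevalence-matching threshold stage is designed to neutralise.
#'
#' @param n_groups Number of severity groups K.
#' @param group_sizes Integer vector of K group sizes. Defaults to
#'   492, 205, 291, 303.
#' @param items_per_domain Integer vector, items aggregated into each domain
#'   (recycled to p).
#' @param severity_offsets Numeric vector of K non-decreasing shifts applied
#'   to the ordinal item location per group.
#' @param ground_truth A single `ground_truth_network` shared by all groups,
#'   or a list of K of them.
#' @param item_base Baseline location of the item cumulative-logit emission.
#' @param latent_effect Added location when the latent domain state is 1.
#' @param cut2 Second cumulative-logit cutpoint (the 1 vs 2 boundary; the
#'   first cutpoint is absorbed into `item_base`).
#' @param seed Master seed; all randomness is derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_groups = 4L,
                        group_sizes = c(492L, 205L, 291L, 303L),
                        items_per_domain = 4L,
                        severity_offsets = c(0, 0.5, 1.0, 1.5),
                        ground_truth = default_ground_truth(),
                        item_base = -1.2, latent_effect = 3.5, cut2 = 2.2,
                        seed = 1L) {
  if (n_groups < 1) stop("n_groups: must be >= 1")
  if (length(group_sizes) != n_groups)
    stop("group_sizes: need one size per group (", n_groups, ")")
  if (any(group_sizes < 1)) stop("group_sizes: all must be >= 1")
  if (length(severity_offsets) != n_groups)
    stop("severity_offsets: need one offset per group")
  if (is.unsorted(severity_offsets))
    stop("severity_offsets: must be non-decreasing across groups")
  if (inherits(ground_truth, "ground_truth_network"))
    ground_truth <- rep(list(ground_truth), n_groups)
  if (length(ground_truth) != n_groups)
    stop("ground_truth: supply one network, or one per group")
  p <- ground_truth[[1]]$p
  if (!all(vapply(ground_truth, function(g) g$p, 0L) == p))
    stop("ground_truth: all group networks must share the node set")
  items_per_domain <- rep_len(as.integer(items_per_domain), p)
  if (any(items_per_domain < 1)) stop("items_per_domain: all must be >= 1")
  structure(list(n_groups = as.integer(n_groups),
                 group_sizes = as.integer(group_sizes),
                 items_per_domain = items_per_domain,
                 severity_offsets = as.numeric(severity_offsets),
                 ground_truth = ground_truth,
                 item_base = item_base, latent_effect = latent_effect,
                 cut2 = cut2, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate an ordinal symptom cohort from a specification
#'
#' Pure function of spec + seed: per group, latent domain states are sampled
#' exactly from the group's Ising network, then each item score in \{0,1,2\}
#' is drawn from a cumulative-logit distribution with location
#' `item_base + latent_effect * state + severity_offset`.
#'
#' @param spec A `cohort_spec`.
#' @return A `symptom_cohort`: list with `item_scores` (individuals x items),
#'   `domain_scores` (individuals x domains, the per-domain item sums),
#'   `domain_map` (item -> domain name), `group_labels`, and `domains`.
#' @export
generate_ordinal_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  domains <- spec$ground_truth[[1]]$nodes
  p <- length(domains)
  domain_map <- rep(domains, times = spec$items_per_domain)
  item_names <- unlist(lapply(seq_len(p), function(d)
    paste0(domains[d], "_it", seq_len(spec$items_per_domain[d]))))
  names(domain_map) <- item_names

  rows <- vector("list", spec$n_groups)
  for (g in seq_len(spec$n_groups)) {
    n_g <- spec$group_sizes[g]
    z <- sample_ising_exact(spec$ground_truth[[g]], n_g,
                            seed = derive_seed(spec$seed, 1L, g))
    set.seed(derive_seed(spec$seed, 2L, g))
    loc <- spec$item_base + spec$latent_effect * z[, domain_map, drop = FALSE] +
      spec$severity_offsets[g]
    p_ge1 <- stats::plogis(loc)           # P(score >= 1)
    p_eq2 <- stats::plogis(loc - spec$cut2)  # P(score = 2), cut2 > 0
    u <- matrix(stats::runif(n_g * length(domain_map)), n_g)
    rows[[g]] <- (u < p_ge1) + (u < p_eq2)
  }
  item_scores <- do.call(rbind, rows)
  colnames(item_scores) <- item_names
  storage.mode(item_scores) <- "integer"
  structure(list(item_scores = item_scores,
                 domain_scores = aggregate_domains(item_scores, domain_map),
                 domain_map = domain_map,
                 group_labels = rep(seq_len(spec$n_groups),
                                    times = spec$group_sizes),
                 domains = domains, spec = spec),
            class = "symptom_cohort")
}

#' @export
print.symptom_cohort <- function(x, ...) {
  cat("Symptom cohort: ", nrow(x$item_scores), " individuals, ",
      length(x$domains), " domains (", ncol(x$item_scores), " items), ",
      length(unique(x$group_labels)), " groups\n", sep = "")
  invisible(x)
}

#' Aggregate item scores into domain sum scores
#'
#' @param item_scores Integer matrix (individuals x items) with entries in
#'   \{0, 1, 2\}.
#' @param domain_map Character vector mapping each item (by position or by
#'   column name) to a domain.
#' @return Integer matrix individuals x domains of item sums.
#' @export
aggregate_domains <- function(item_scores, domain_map) {
  item_scores <- as.matrix(item_scores)
  if (length(domain_map) != ncol(item_scores))
    stop("domain_map: every item must be mapped to exactly one domain (",
         ncol(item_scores), " items, ", length(domain_map), " mappings)")
  if (anyNA(domain_map)) stop("domain_map: unmapped item (NA in map)")
  domains <- unique(domain_map)
  out <- vapply(domains, function(d)
    rowSums(item_scores[, domain_map == d, drop = FALSE]),
    numeric(nrow(item_scores)))
  out <- matrix(out, nrow = nrow(item_scores),
                dimnames = list(rownames(item_scores), domains))
  storage.mode(out) <- "integer"
  out
}

#' Write / read a cohort as plain-text tables
#'
#' Two CSVs (item scores and domain scores, each with individual id and group
#' columns) plus a JSON sidecar holding the item-to-domain map.
#'
#' @param cohort A `symptom_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns the directory invisibly; `read_cohort`
#'   returns a `symptom_cohort` (without the generating spec).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "symptom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- seq_len(nrow(cohort$item_scores))
  utils::write.csv(data.frame(id = id, group = cohort$group_labels,
                              cohort$item_scores, check.names = FALSE),
                   file.path(dir, "items.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = id, group = cohort$group_labels,
                              cohort$domain_scores, check.names = FALSE),
                   file.path(dir, "domains.csv"), row.names = FALSE)
  jsonlite::write_json(list(domain_map = as.list(cohort$domain_map),
                            domains = cohort$domains),
                       file.path(dir, "cohort_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  items <- utils::read.csv(file.path(dir, "items.csv"), check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "cohort_meta.json"))
  domain_map <- unlist(meta$domain_map)
  item_scores <- as.matrix(items[, names(domain_map), drop = FALSE])
  storage.mode(item_scores) <- "integer"
  if (anyNA(item_scores))
    stop("missing item scores are not allowed; exclude incomplete individuals")
  structure(list(item_scores = item_scores,
                 domain_scores = aggregate_domains(item_scores, domain_map),
                 domain_map = domain_map,
                 group_labels = as.integer(items$group),
                 domains = unlist(meta$domains), spec = NULL),
            class = "symptom_cohort")
}
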