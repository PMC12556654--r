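.tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
                "species")
.rank_prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                    order = "o__", family = "f__", genus = "g__",
                    species = "s__")

rank_index <- function(rank) {
  i <- match(rank, .tax_ranks)
  abort_if(is.na(i), paste("unknown taxonomy rank:", rank), "gh_rank_error")
  i
}

# extract the label at `rank` from a "k__...|p__...|g__..." lineage string
lineage_at <- function(lineages, rank) {
  pref <- .rank_prefixes[[rank]]
  purrr::map_chr(strsplit(lineages, "|", fixed = TRUE), function(parts) {
    hit <- grep(paste0("^", pref), parts, value = TRUE)
    if (length(hit)) sub(pref, "", hit[1]) else NA_character_
  })
}

# truncate a lineage string at `rank`
lineage_truncate <- function(lineages, rank) {
  i <- rank_index(rank)
  prefs <- .rank_prefixes[seq_len(i)]
  purrr::map_chr(strsplit(lineages, "|", fixed = TRUE), function(parts) {
    keep <- parts[substr(parts, 1, 3) %in% prefs]
    paste(keep, collapse = "|")
  })
}

#' Construct a relative-abundance table
#'
#' Lineage-string rows by sample columns, MetaPhlAn-style. Abundances are
#' fractions; per-sample sums must lie in (0, 1.0001] (tables summing to
#' ~100 are auto-rescaled by [read_abundance_tsv()] before reaching this
#' constructor). Sums slightly below 1 (>= `sum_tolerance`) are accepted and
#' renormalized.
#'
#' @param taxa Character vector of lineage strings.
#' @param abundances Numeric matrix, rows = taxa, columns = samples.
#' @param level Taxonomy rank of the rows (default `"genus"`).
#' @param sum_tolerance Minimum accepted per-sample sum before renormalizing.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(taxa, abundances, level = "genus",
                            sum_tolerance = 0.97) {
  abundances <- as.matrix(abundances)
  stopifnot(length(taxa) == nrow(abundances))
  rank_index(level)
  abort_if(any(abundances < 0), "abundances must be non-negative",
           "gh_domain_error")
  sums <- colSums(abundances)
  abort_if(any(sums <= 0), "every sample must have positive total abundance",
           "gh_domain_error")
  abort_if(any(sums < sum_tolerance | sums > 1.0001),
           sprintf("per-sample sums must lie in [%.3g, 1.0001]; got range [%.4g, %.4g]",
                   sum_tolerance, min(sums), max(sums)),
           "gh_domain_error")
  abundances <- sweep(abundances, 2, sums, "/")
  rownames(abundances) <- taxa
  if (is.null(colnames(abundances)))
    colnames(abundances) <- paste0("sample_", seq_len(ncol(abundances)))
  structure(list(taxa = taxa, abundances = abundances, level = level),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d taxa (%s level) x %d samples\n",
              length(x$taxa), x$level, ncol(x$abundances)))
  invisible(x)
}

#' Aggregate an abundance table to a coarser taxonomic level
#'
#' Sums abundances within groups defined by the lineage truncated at the
#' target rank; per-sample totals are preserved exactly.
#'
#' @param table An [abundance_table()].
#' @param target_level Rank at or above the table's level.
#' @return An [abundance_table()] at `target_level`.
#' @export
aggregate_abundance <- function(table, target_level) {
  stopifnot(inherits(table, "abundance_table"))
  ti <- rank_index(target_level)
  si <- rank_index(table$level)
  abort_if(ti > si,
           sprintf("cannot aggregate %s-level table to finer %s level",
                   table$level, target_level),
           "gh_rank_error")
  if (ti == si) return(table)
  groups <- lineage_truncate(table$taxa, target_level)
  agg <- rowsum(table$abundances, group = groups, reorder = TRUE)
  abundance_table(rownames(agg), agg, level = target_level)
}

#' Fraction of biomass represented by characterized taxa
#'
#' For each sample, the summed relative abundance of the taxa for which a
#' measured representative strain exists, divided by the total abundance.
#' Taxa may be given as full lineage strings or as bare labels at the
#' table's level.
#'
#' @param table An [abundance_table()].
#' @param represented Character vector of represented taxa.
#' @return List with `per_sample` (named numeric) and `mean`.
#' @export
coverage <- function(table, represented) {
  stopifnot(inherits(table, "abundance_table"))
  idx <- match_taxa(table, represented)
  if (!any(idx)) warning("no represented taxa found in table: coverage is 0")
  per_sample <- colSums(table$abundances[idx, , drop = FALSE]) /
    colSums(table$abundances)
  list(per_sample = per_sample, mean = mean(per_sample))
}

# logical index of table rows matching `taxa` (lineages or bare labels)
match_taxa <- function(table, taxa) {
  labels <- lineage_at(table$taxa, table$level)
  labels <- ifelse(is.na(labels), table$taxa, labels)  # bare-label tables
  bare <- ifelse(grepl("__", taxa),
                 lineage_at(taxa, table$level), taxa)
  labels %in% bare
}

#' Construct a community metabolic profile
#'
#' Abundance-weighted per-biomass rates of a whole community:
#' `epsilon_tot` (total fermentation product excretion, mmol/g dry biomass),
#' per-product rates `e_w`, the carbohydrate demand (mmol hexose equivalents
#' per g biomass produced) and its reciprocal, the biomass yield `y_carb`
#' (g biomass per mmol hexose).
#'
#' @param e_w Named numeric per-product community rates (mmol/g).
#' @param carb_demand mmol hexose equivalents per g biomass (> 0).
#' @param sds Named numeric uncertainties (products plus `"carb_demand"`).
#' @param coverage Fraction of biomass represented by measured strains.
#' @param level Taxonomy rank of the weighting.
#' @param mode Weighting mode used (see [weight_profiles()]).
#' @return Object of class `community_profile`.
#' @export
community_profile <- function(e_w, carb_demand, sds = NULL, coverage = NA_real_,
                              level = "genus", mode = "renormalize") {
  e_w <- canonical_products(e_w)
  abort_if(carb_demand <= 0, "carb_demand must be positive", "gh_domain_error")
  epsilon_tot <- sum(pmax(e_w, 0)) + sum(pmin(e_w["acetate"], 0))
  structure(
    list(e_w = e_w, epsilon_tot = epsilon_tot, carb_demand = carb_demand,
         y_carb = 1 / carb_demand,
         sds = sds %||% c(canonical_products(NULL), carb_demand = 0,
                          epsilon_tot = 0),
         coverage = coverage, level = level, mode = mode),
    class = "community_profile"
  )
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("<community_profile> (%s level, %s mode): epsilon_tot = %.2f mmol/g, carb demand = %.2f mmol hexose/g, coverage = %.1f%%\n",
              x$level, x$mode, x$epsilon_tot, x$carb_demand,
              100 * x$coverage))
  invisible(x)
}

#' Abundance-weight strain profiles into a community profile
#'
#' Restricts a sample's abundance vector to the taxa with a measured
#' representative, renormalizes it to sum 1, and averages the strain rate
#' profiles with those weights. Multiple strains mapping to the same taxon
#' are first averaged without weighting. The pre-renormalization coverage is
#' recorded.
#'
#' In `"renormalize"` mode (default) the unrepresented biomass is assumed to
#' behave like the represented average; in `"coverage_discount"` mode all
#' community rates are additionally multiplied by the coverage, treating
#' unrepresented biomass as metabolically silent (a sensitivity bound).
#'
#' @param profiles List of [strain_rate_profile()] objects with lineages.
#' @param abundances Named numeric vector: one sample's relative abundances,
#'   names either bare labels at `level` or full lineage strings.
#' @param level Taxonomy rank at which to match strains to abundances.
#' @param mode `"renormalize"` or `"coverage_discount"`.
#' @return A [community_profile()].
#' @export
weight_profiles <- function(profiles, abundances, level = "genus",
                            mode = c("renormalize", "coverage_discount")) {
  mode <- match.arg(mode)
  stopifnot(all(purrr::map_lgl(profiles, inherits, "strain_rate_profile")))
  nm <- names(abundances)
  abort_if(is.null(nm), "abundances must be a named vector", "gh_domain_error")
  labels <- ifelse(grepl("__", nm), lineage_at(nm, level), nm)

  strain_label <- purrr::map_chr(profiles, function(p) {
    lab <- if (level %in% names(p$lineage)) p$lineage[[level]] else NA_character_
    abort_if(is.na(lab),
             sprintf("profile %s has no %s-level lineage", p$strain_id, level),
             "gh_domain_error")
    lab
  })

  # average strains within each taxon, unweighted
  by_taxon <- split(profiles, strain_label)
  taxon_rates <- purrr::map(by_taxon, function(ps) {
    e_mat <- do.call(rbind, purrr::map(ps, function(p) p$e))
    list(e = colMeans(e_mat),
         u_hex = mean(purrr::map_dbl(ps, function(p) p$u_hexose)),
         e_sd = apply(do.call(rbind, purrr::map(ps, function(p)
           p$sds[fermentation_products])), 2, mean),
         u_sd = mean(purrr::map_dbl(ps, function(p) p$sds[["u"]] *
                                      .hexose_units[[p$sugar]])))
  })

  present <- labels %in% names(taxon_rates) & abundances > 0
  abort_if(!any(present),
           paste("no strain represents any abundant taxon; missing:",
                 paste(utils::head(unique(labels), 10), collapse = ", ")),
           "gh_no_representation")
  cov <- sum(abundances[present]) / sum(abundances)
  a <- abundances[present]
  a <- a / sum(a)
  lab <- labels[present]

  e_w <- Reduce(`+`, purrr::map(seq_along(a), function(i)
    a[[i]] * taxon_rates[[lab[i]]]$e))
  carb_demand <- sum(purrr::map_dbl(seq_along(a), function(i)
    a[[i]] * taxon_rates[[lab[i]]]$u_hex))
  # weighted rates: Var = sum a_i^2 var_i (independent strain uncertainties)
  e_sd <- sqrt(Reduce(`+`, purrr::map(seq_along(a), function(i)
    (a[[i]] * taxon_rates[[lab[i]]]$e_sd)^2)))
  carb_sd <- sqrt(sum(purrr::map_dbl(seq_along(a), function(i)
    (a[[i]] * taxon_rates[[lab[i]]]$u_sd)^2)))

  if (mode == "coverage_discount") {
    e_w <- e_w * cov
    e_sd <- e_sd * cov
  }
  eps_sd <- sqrt(sum(e_sd^2))
  community_profile(
    e_w = e_w, carb_demand = carb_demand,
    sds = c(canonical_products(e_sd), carb_demand = unname(carb_sd),
            epsilon_tot = unname(eps_sd)),
    coverage = cov, level = level, mode = mode
  )
}

#' Read a MetaPhlAn-style abundance TSV
#'
#' First column holds full lineage strings (`k__...|p__...|g__...`),
#' remaining columns one per sample. Values may be fractions or percentages;
#' the scale is auto-detected from column sums and rescaled to fractions
#' (with a message).
#'
#' @param path TSV path.
#' @param level Rank at which the rows are resolved.
#' @return An [abundance_table()].
#' @export
read_abundance_tsv <- function(path, level = "genus") {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  taxa <- tb[[1]]
  mat <- as.matrix(tb[-1])
  sums <- colSums(mat)
  if (stats::median(sums) > 1.5) {
    message("column sums near ", signif(stats::median(sums), 3),
            ": interpreting values as percentages")
    mat <- mat / 100
  }
  abundance_table(taxa, mat, level = level)
}

#' Write an abundance table as TSV
#'
#' @param table An [abundance_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_abundance_tsv <- function(table, path) {
  tb <- tibble::as_tibble(table$abundances)
  tb <- dplyr::bind_cols(tibble::tibble(clade_name = table$taxa), tb)
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Serialize a community profile to JSON
#'
#' @param profile A [community_profile()].
#' @param path Output path.
#' @param provenance Optional named list recorded alongside the numbers.
#' @return The path, invisibly.
#' @export
write_community_json <- function(profile, path, provenance = list()) {
  jsonlite::write_json(
    list(epsilon_tot_mmol_per_g = profile$epsilon_tot,
         e_w_mmol_per_g = as.list(profile$e_w),
         carb_demand_mmol_hexose_per_g = profile$carb_demand,
         y_carb_g_per_mmol_hexose = profile$y_carb,
         sds = as.list(profile$sds),
         coverage_fraction = profile$coverage,
         level = profile$level, mode = profile$mode,
         provenance = provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
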