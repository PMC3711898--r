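#' Load the packaged yeast central-carbon-metabolism reference table
#'
#' Reads the packaged strain-level physiology table (one row per batch
#' cultivation run of a *Saccharomycetaceae* strain or control species:
#' ethanol and biomass yields on glucose, specific glucose consumption and
#' ethanol production rates, and maximum specific growth rate), or a
#' user-supplied TSV in the same layout.
#'
#' Replicate runs of the same strain carry an `A1`/`A2` (or `B1`/`B2`)
#' suffix on `species_label`. Values are kept exactly as printed in the
#' source table, including two rows (`Kaz. exiguus`, `Tor. franciscae`)
#' whose rate columns are internally inconsistent; see
#' [build_analysis_set()] for the documented repair option.
#'
#' @param path Path to a TSV file. Defaults to the packaged table.
#' @param repaired Logical; if `TRUE`, apply the documented within-row
#'   permutation repair to the two internally inconsistent rows (see
#'   Details). Default `FALSE`: values exactly as printed.
#'
#' @details
#' The repair treats each suspect row as a column permutation of correct
#' values and selects the permutation that best satisfies the two internal
#' identities that hold for every other row of the table:
#' `q_E / q_S ~ Y_E/S` (exponential-phase ethanol per glucose) and
#' `mu / Y_X/S ~ q_S`. Concretely: `Kaz. exiguus` becomes ethanol yield
#' 0.43, biomass yield 0.18, consumption rate 1.75, production rate 0.74,
#' growth rate 0.43; `Tor. franciscae` has its consumption and production
#' rate columns swapped.
#'
#' @return A tibble with one row per cultivation run and columns
#'   `species_label`, `strain_key`, `genus_code`, `y_collection`, `cbs`,
#'   `other_collection`, `ethanol_yield`, `biomass_yield`, `glc_cons_rate`,
#'   `etoh_prod_rate`, `growth_rate`.
#' @seealso [build_analysis_set()], [assign_phylo_group()]
#' @export
#' @examples
#' runs <- load_reference_table()
#' nrow(runs) # 66 cultivation runs
load_reference_table <- function(path = NULL, repaired = FALSE) {
  if (is.null(path)) {
    path <- system.file("extdata", "yeast_carbon_metabolism.tsv",
                        package = "crabtree", mustWork = TRUE)
  }
  numeric_cols <- c("ethanol_yield", "biomass_yield", "glc_cons_rate",
                    "etoh_prod_rate", "growth_rate")
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       comment = "#", progress = FALSE)
  expected <- c("species_label", "y_collection", "cbs", "other_collection",
                numeric_cols)
  missing_cols <- setdiff(expected, names(d))
  if (length(missing_cols) > 0) {
    stop("reference table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (cl in numeric_cols) {
    v <- suppressWarnings(as.numeric(d[[cl]]))
    bad <- which(is.na(v) & !is.na(d[[cl]]) & d[[cl]] != "")
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value in column '%s' at data row %d ('%s')",
                   cl, bad[1], d[[cl]][bad[1]]))
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column '%s' at data row %d",
                   cl, which(is.na(v))[1]))
    }
    d[[cl]] <- v
  }
  if (any(d$species_label == "" | is.na(d$species_label))) {
    stop("empty species_label at data row ",
         which(d$species_label == "" | is.na(d$species_label))[1])
  }
  d <- dplyr::mutate(
    d,
    genus_code = substr(.data$species_label, 1, 3),
    .after = "species_label"
  )
  bad_genus <- setdiff(unique(d$genus_code), names(phylo_group_map()))
  if (length(bad_genus) > 0) {
    stop("unknown genus prefix in species_label: ",
         paste(bad_genus, collapse = ", "))
  }
  d <- dplyr::mutate(d, strain_key = make_strain_key(
    .data$species_label, .data$cbs, .data$other_collection,
    .data$y_collection
  ), .after = "species_label")
  if (repaired) d <- repair_reference_rows(d)
  tibble::as_tibble(d)
}

# strain key = species label with a trailing replicate token (" A1", " B2",
# ...) stripped, plus the most specific collection id, so that distinct
# strains of the same species (e.g. the two L. kluyverii isolates, the
# three K. marxianus isolates) stay distinct.
make_strain_key <- function(species_label, cbs, other, y_collection) {
  base <- sub("\\s[AB][12]$", "", species_label)
  id <- dplyr::case_when(
    !is.na(cbs) & cbs != "" ~ paste0("CBS", cbs),
    !is.na(other) & other != "" ~ other,
    TRUE ~ y_collection
  )
  paste(base, id)
}

repair_reference_rows <- function(d) {
  i <- d$species_label == "Kaz. exiguus"
  if (any(i)) {
    d$ethanol_yield[i] <- 0.43
    d$biomass_yield[i] <- 0.18
    d$glc_cons_rate[i] <- 1.75
    d$etoh_prod_rate[i] <- 0.74
    d$growth_rate[i] <- 0.43
  }
  j <- grepl("^Tor\\. franciscae", d$species_label)
  if (any(j)) {
    cons <- d$glc_cons_rate[j]
    d$glc_cons_rate[j] <- d$etoh_prod_rate[j]
    d$etoh_prod_rate[j] <- cons
  }
  d
}

#' Genus-prefix to phylogenetic-group mapping
#'
#' The four phylogenetic groups used in the comparative statistics:
#' group 1 *Kluyveromyces* and *Eremothecium*; group 2 *Lachancea*,
#' *Torulaspora* and *Zygotorulaspora*; group 3 *Vanderwaltozyma* and
#' *Tetrapisispora*; group 4 *Saccharomyces*, *Kazachstania*,
#' *Naumovozyma* and *Nakaseomyces*. The fructophilic *Zygosaccharomyces*
#' genus and the non-*Saccharomycetaceae* controls are never grouped
#' (`NA`).
#'
#' @return Named integer vector mapping 3-letter genus prefixes to group
#'   id (1-4) or `NA` for excluded/control genera.
#' @export
phylo_group_map <- function() {
  c(Klu = 1L, Ere = 1L,
    Lac = 2L, Tor = 2L, Zto = 2L,
    Van = 3L, Tet = 3L,
    Sac = 4L, Kaz = 4L, Nau = 4L, Nak = 4L,
    Zsa = NA_integer_, Deb = NA_integer_, Dek = NA_integer_,
    Pic = NA_integer_, Sch = NA_integer_)
}

#' Assign the phylogenetic comparison group for a genus
#'
#' @param genus_code Character vector of 3-letter genus prefixes
#'   (e.g. `"Sac"`, `"Klu"`).
#' @param species_label Optional species labels, used only for error
#'   messages.
#' @return Integer vector of group ids (1-4), `NA` for excluded or
#'   control genera.
#' @export
#' @examples
#' assign_phylo_group(c("Klu", "Sac", "Sch")) # 1, 4, NA
assign_phylo_group <- function(genus_code, species_label = genus_code) {
  map <- phylo_group_map()
  unknown <- !(genus_code %in% names(map))
  if (any(unknown)) {
    stop("unknown genus code: ",
         paste(unique(species_label[unknown]), collapse = ", "))
  }
  unname(map[genus_code])
}

#' Build the strain-level comparative analysis set
#'
#' Collapses replicate cultivation runs to one record per strain
#' (arithmetic mean of each numeric field over the run-level values) and
#' applies the exclusion rules of the comparative analysis: the
#' fructophilic *Zygosaccharomyces* genus, the cockroach-gut isolate
#' *Tet. blattae*, and the five non-*Saccharomycetaceae* control strains
#' (*Debaryomyces*, *Dekkera*, *Pichia* x2, *Schizosaccharomyces*) are
#' dropped. The result is the 37-strain set over which the grouped
#' statistics are defined, with phylogenetic group ids attached.
#'
#' Idempotent: applying it to its own output returns the same records.
#'
#' @param records Run-level tibble from [load_reference_table()] (or an
#'   already collapsed analysis set).
#' @return Tibble with one row per strain: `strain_key`, `species`,
#'   `genus_code`, `group`, `n_runs`, and the five numeric metrics.
#' @export
#' @examples
#' aset <- build_analysis_set(load_reference_table())
#' nrow(aset) # 37 strains
#' table(aset$group) # 10, 8, 4, 15
build_analysis_set <- function(records) {
  numeric_cols <- c("ethanol_yield", "biomass_yield", "glc_cons_rate",
                    "etoh_prod_rate", "growth_rate")
  if (!"species_label" %in% names(records) && "species" %in% names(records)) {
    records$species_label <- records$species
  }
  if (!"n_runs" %in% names(records)) records$n_runs <- 1L
  stopifnot(all(c("species_label", "strain_key", "genus_code",
                  numeric_cols) %in% names(records)))
  keep <- records %>%
    dplyr::filter(
      !.data$genus_code %in% c("Zsa", "Deb", "Dek", "Pic", "Sch"),
      !grepl("^Tet\\. blattae", .data$species_label)
    )
  over <- keep %>%
    dplyr::count(.data$strain_key) %>%
    dplyr::filter(.data$n > 2)
  if (nrow(over) > 0) {
    warning("more than 2 replicate runs for strain(s): ",
            paste(over$strain_key, collapse = ", "),
            "; averaging over all runs")
  }
  out <- keep %>%
    dplyr::group_by(.data$strain_key) %>%
    dplyr::summarise(
      species = sub("\\s[AB][12]$", "", .data$species_label[1]),
      genus_code = .data$genus_code[1],
      dplyr::across(dplyr::all_of(numeric_cols), mean),
      n_runs = sum(.data$n_runs),
      .groups = "drop"
    ) %>%
    dplyr::mutate(group = assign_phylo_group(.data$genus_code, .data$species),
                  .after = "genus_code")
  if (anyNA(out$group)) {
    stop("excluded genus survived filtering: ",
         paste(unique(out$genus_code[is.na(out$group)]), collapse = ", "))
  }
  out
}
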