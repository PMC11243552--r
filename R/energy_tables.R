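#' Ingest a docking energy table
#'
#' Reads a delimited file with one row per ligand and the docking energy
#' decomposition: protein-ligand energy, total energy, steric, van der
#' Waals and hydrogen-bond terms, and the binding affinity (all kcal/mol).
#' Header matching is tolerant of punctuation and case (for example
#' `"E_protein-ligand"`, `"van der Waals"`, `"Binding Affinity"`); a
#' glycone/series column is optional and is used to derive ligand ids.
#' Unicode minus signs are normalized to ASCII before numeric parsing.
#'
#' @param path CSV/TSV file path.
#' @param sep field separator; `NULL` picks `\t` for `.tsv`, `,` otherwise.
#' @param default_series series assigned when the table has no
#'   glycone/series column (e.g. a single-series table).
#' @return data.frame of class `energy_table` with columns `id, ligand,
#'   series, e_protein_ligand, e_total, steric, vdw, hbond,
#'   binding_affinity`.
#' @export
ingest_energy_table <- function(path, sep = NULL,
                                default_series = "difluoro") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(ascii_minus(x)))
  hdr <- norm(names(raw))
  pick <- function(patterns, required = TRUE, label = patterns[1]) {
    for (p in patterns) {
      hit <- which(hdr == p)
      if (length(hit)) return(hit[1])
    }
    if (required)
      stop("energy table missing required column: ", label, call. = FALSE)
    NA_integer_
  }
  i_lig <- pick(c("ligand", "name"), label = "ligand")
  i_ser <- pick(c("series", "glycone"), required = FALSE)
  i_epl <- pick(c("eproteinligand", "proteinligand", "eprotligand"),
                label = "E_protein-ligand")
  i_tot <- pick(c("etotal", "total"), label = "E_total")
  i_ste <- pick("steric", label = "steric")
  i_vdw <- pick(c("vdw", "vanderwaals"), label = "van der Waals")
  i_hb <- pick(c("hbond", "hydrogenbond", "hydrogenbonds"),
               label = "hydrogen bond")
  i_ba <- pick(c("bindingaffinity", "affinity"), label = "binding affinity")
  series_map <- c(none = "none", "-" = "none", ribose = "ribose",
                  deoxyribose = "deoxyribose",
                  "2deoxyribose" = "deoxyribose",
                  difluoro = "difluoro",
                  "2deoxy22difluororibose" = "difluoro")
  series <- if (!is.na(i_ser)) {
    key <- norm(as.character(raw[[i_ser]]))
    key[!nzchar(key)] <- "-"
    mapped <- series_map[key]
    ifelse(is.na(mapped), as.character(raw[[i_ser]]), mapped)
  } else rep(default_series, nrow(raw))
  num_cols <- list(e_protein_ligand = i_epl, e_total = i_tot,
                   steric = i_ste, vdw = i_vdw, hbond = i_hb,
                   binding_affinity = i_ba)
  out <- data.frame(ligand = trimws(as.character(raw[[i_lig]])),
                    series = series, stringsAsFactors = FALSE)
  for (nm in names(num_cols)) {
    vals <- parse_num(raw[[num_cols[[nm]]]])
    bad <- which(is.na(vals))
    if (length(bad))
      stop("non-numeric value in column '", nm, "', row ", bad[1],
           ": '", raw[bad[1], num_cols[[nm]]], "'", call. = FALSE)
    out[[nm]] <- vals
  }
  code <- pattern_code(out$ligand)
  out$id <- ifelse(is.na(code), paste0(out$ligand, "_", out$series),
                   paste0(code, "_", out$series))
  out <- out[, c("id", "ligand", "series", names(num_cols))]
  class(out) <- c("energy_table", "data.frame")
  out
}

#' Packaged docking energy tables for the three kinase targets
#'
#' Verbatim transcriptions of the docking energy decompositions shipped
#' with the package: `"ck2a"` (CK2alpha, 40 ligands: all four glycone
#' series), `"pim1"` (PIM-1, the 10-member 2'-deoxy-2',2'-difluoro-ribose
#' series) and `"rio1"` (RIO1, same series). Energies in kcal/mol.
#'
#' @param table `"ck2a"`, `"pim1"` or `"rio1"`.
#' @return an `energy_table` data.frame (40, 10 and 10 rows respectively).
#' @examples
#' nrow(load_packaged_tables("ck2a"))
#' @export
load_packaged_tables <- function(table = c("ck2a", "pim1", "rio1")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0(table, "_docking.csv"),
                      package = "ligandscape", mustWork = TRUE)
  ingest_energy_table(path, default_series = "difluoro")
}

#' Extremal record within a (filtered) energy table
#'
#' @param records an `energy_table` data.frame.
#' @param series optional series filter (e.g. `"difluoro"`).
#' @param field numeric column to rank (e.g. `"binding_affinity"`).
#' @param mode `"min"` (most negative, i.e. strongest for energies) or
#'   `"max"`.
#' @return list with `ligand` (all tied ids), `value` and the matching
#'   rows.
#' @export
series_extremum <- function(records, series = NULL,
                            field = "binding_affinity",
                            mode = c("min", "max")) {
  mode <- match.arg(mode)
  if (!field %in% names(records))
    stop("unknown field: ", field, call. = FALSE)
  if (!is.null(series)) records <- records[records$series %in% series, ,
                                           drop = FALSE]
  if (nrow(records) == 0L)
    stop("no records after series filter", call. = FALSE)
  v <- records[[field]]
  ext <- if (mode == "min") min(v) else max(v)
  hit <- which(abs(v - ext) < 1e-12)
  list(ligand = records$id[hit], name = records$ligand[hit], value = ext,
       rows = records[hit, , drop = FALSE])
}

#' Energy-table rows as binding fingerprints
#'
#' One fingerprint per ligand whose keys are the energy components; used
#' to feed the mode-distance machinery with energy-derived entries.
#'
#' @param records an `energy_table`.
#' @param components which numeric columns become fingerprint keys.
#' @return named list of `binding_fp` (source `"energy_table"`).
#' @export
energy_fingerprints <- function(records,
                                components = c("e_protein_ligand",
                                               "steric", "vdw", "hbond")) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    binding_fingerprint(setNames(as.numeric(records[i, components]),
                                 components),
                        ligand_id = records$id[i], source = "energy_table")
  })
  names(out) <- records$id
  out
}
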