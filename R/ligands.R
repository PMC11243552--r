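#' Ligand objects
#'
#' A ligand couples an identifier with its glycone series, the halogenation
#' pattern at the four benzimidazole ring positions (R1--R4, i.e. ring
#' positions 4,5,6,7), an optional line-notation (SMILES) structure, and an
#' optional 3D conformer.
#'
#' @param id unique, nonempty ligand identifier.
#' @param series glycone at N(1): one of `"none"`, `"ribose"`,
#'   `"deoxyribose"` (2'-deoxyribose) or `"difluoro"`
#'   (2'-deoxy-2',2'-difluoro-ribose).
#' @param substituents named character vector with names exactly
#'   `R1,R2,R3,R4`, values in `H,F,Cl,Br,I`.
#' @param structure optional SMILES string.
#' @param conformer optional data.frame with columns `element,x,y,z`
#'   (Angstrom); at least one atom when present.
#' @return an object of class `ligand`.
#' @export
ligand <- function(id, series = "none",
                   substituents = c(R1 = "H", R2 = "H", R3 = "H", R4 = "H"),
                   structure = NULL, conformer = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("ligand id must be a nonempty string", call. = FALSE)
  series <- match.arg(series, ligand_series())
  if (!setequal(names(substituents), c("R1", "R2", "R3", "R4")))
    stop("substituent positions must be exactly R1, R2, R3, R4", call. = FALSE)
  substituents <- substituents[c("R1", "R2", "R3", "R4")]
  bad <- !substituents %in% c("H", "F", "Cl", "Br", "I")
  if (any(bad))
    stop("invalid substituent element(s): ",
         paste(substituents[bad], collapse = ", "), call. = FALSE)
  if (!is.null(conformer)) {
    conformer <- as.data.frame(conformer)
    need <- c("element", "x", "y", "z")
    if (!all(need %in% names(conformer)) || nrow(conformer) < 1L)
      stop("conformer needs >=1 atom with columns element, x, y, z",
           call. = FALSE)
  }
  structure(list(id = id, series = series, substituents = substituents,
                 structure = structure, conformer = conformer),
            class = "ligand")
}

#' @export
print.ligand <- function(x, ...) {
  subs <- paste0(names(x$substituents), "=", x$substituents, collapse = " ")
  cat("<ligand>", x$id, "\n  series:", x$series, "\n  substituents:", subs,
      "\n")
  if (!is.null(x$structure)) cat("  structure:", x$structure, "\n")
  if (!is.null(x$conformer))
    cat("  conformer:", nrow(x$conformer), "atoms\n")
  invisible(x)
}

ligand_series <- function() c("none", "ribose", "deoxyribose", "difluoro")

# the ten designed halogenation patterns at ring positions 4 (R1), 5 (R2),
# 6 (R3) and 7 (R4)
halogenation_patterns <- function() {
  data.frame(
    code = c("4567-tetraBr", "4567-tetraCl", "4567-tetraI",
             "56-diBr", "56-diCl", "56-diI",
             "56-diBr-47-diCl", "56-diBr-47-diI",
             "56-diI-47-diBr", "56-diI-47-diCl"),
    name = c("4,5,6,7-tetrabromo-", "4,5,6,7-tetrachloro-",
             "4,5,6,7-tetraiodo-", "5,6-dibromo-", "5,6-dichloro-",
             "5,6-diiodo-", "5,6-dibromo,4,7-dichloro-",
             "5,6-dibromo,4,7-diiodo-", "5,6-diiodo,4,7-dibromo-",
             "5,6-diiodo,4,7-dichloro-"),
    R1 = c("Br", "Cl", "I", "H", "H", "H", "Cl", "I", "Br", "Cl"),
    R2 = c("Br", "Cl", "I", "Br", "Cl", "I", "Br", "Br", "I", "I"),
    R3 = c("Br", "Cl", "I", "Br", "Cl", "I", "Br", "Br", "I", "I"),
    R4 = c("Br", "Cl", "I", "H", "H", "H", "Cl", "I", "Br", "Cl"),
    stringsAsFactors = FALSE)
}

glycone_smiles <- function(series) {
  switch(series,
         none        = NULL,
         ribose      = "C1OC(CO)C(O)C1O",
         deoxyribose = "C1OC(CO)C(O)C1",
         difluoro    = "C1OC(CO)C(O)C1(F)F")
}

# SMILES for a halogenated benzimidazole with the glycone at N(1)
ligand_smiles <- function(substituents, series) {
  hal <- function(x, core) if (x == "H") core else paste0(core, "(", x, ")")
  first <- if (substituents[["R1"]] == "H") "c1" else
    paste0(substituents[["R1"]], "c1")
  benzo <- paste0(first, hal(substituents[["R2"]], "c"),
                  hal(substituents[["R3"]], "c"),
                  hal(substituents[["R4"]], "c"), "c2c1")
  gly <- glycone_smiles(series)
  if (is.null(gly)) paste0(benzo, "nc[nH]2")
  else paste0(benzo, "ncn2", gly)
}

#' Enumerate the designed ligand library
#'
#' Builds the full designed library: ten halogenation patterns of the
#' benzimidazole ring (4,5,6,7-tetrabromo/-chloro/-iodo; 5,6-dibromo/
#' -chloro/-iodo; and the four mixed 5,6-di/4,7-di patterns) crossed with
#' the four glycone series (no glycone, ribose, 2'-deoxyribose,
#' 2'-deoxy-2',2'-difluoro-ribose), giving 40 ligands. Identifiers are
#' deterministic strings `"<halogen-pattern>_<series>"` (for example
#' `"4567-tetraBr_difluoro"`), in a fixed series-major order.
#'
#' @return list of [ligand] objects (length 40), each with a SMILES
#'   structure.
#' @examples
#' lib <- enumerate_designed_ligands()
#' length(lib)
#' lib[[1]]$id
#' @export
enumerate_designed_ligands <- function() {
  pats <- halogenation_patterns()
  out <- list()
  for (ser in ligand_series()) {
    for (i in seq_len(nrow(pats))) {
      subs <- c(R1 = pats$R1[i], R2 = pats$R2[i],
                R3 = pats$R3[i], R4 = pats$R4[i])
      id <- paste0(pats$code[i], "_", ser)
      out[[id]] <- ligand(id, series = ser, substituents = subs,
                          structure = ligand_smiles(subs, ser))
    }
  }
  out
}

# map a printed pattern name (e.g. "4,5,6,7-tetrabromo-") to its code;
# returns NA for unknown names
pattern_code <- function(name) {
  pats <- halogenation_patterns()
  pats$code[match(trimws(name), pats$name)]
}

#' Parse ligands from a SMILES-lines or SDF file
#'
#' SMILES files hold one record per line, optionally followed by a
#' tab-separated identifier. SDF (V2000) records are read with ChemmineR;
#' when a record carries 3D coordinates the ligand's conformer is
#' populated.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.sdf`/`.mol` vs anything else),
#'   `"smiles"` or `"sdf"`.
#' @return list of [ligand] objects. An empty file yields an empty list
#'   with a warning; an unreadable record raises an error naming its index.
#' @export
parse_ligands <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sdf", "mol")) "sdf" else "smiles"
  }
  if (format == "smiles") parse_smiles_lines(path) else parse_sdf_file(path)
}

parse_smiles_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty ligand file: ", path, call. = FALSE)
    return(list())
  }
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t")[[1]]
    smi <- trimws(parts[1])
    id <- if (length(parts) >= 2 && nzchar(trimws(parts[2])))
      trimws(parts[2]) else paste0("ligand_", i)
    ok <- tryCatch({
      sdf <- smiles_to_sdf(smi)
      nrow(ChemmineR::atomblock(sdf[[1]])) > 0
    }, error = function(e) FALSE)
    if (!ok) stop("unreadable record ", i, " in ", path, ": ", smi,
                  call. = FALSE)
    out[[i]] <- ligand(id, structure = smi)
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

parse_sdf_file <- function(path) {
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    warning("empty ligand file: ", path, call. = FALSE)
    return(list())
  }
  sdfs <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                   error = function(e)
                     stop("unreadable SDF file ", path, ": ",
                          conditionMessage(e), call. = FALSE))
  valid <- ChemmineR::validSDF(sdfs)
  if (any(!valid))
    stop("unreadable record ", which(!valid)[1], " in ", path, call. = FALSE)
  out <- vector("list", length(sdfs))
  for (i in seq_along(sdfs)) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    elements <- gsub("_.*$", "", rownames(ab))
    conf <- NULL
    if (any(abs(ab[, 3]) > 1e-8)) {  # nonzero z: genuine 3D record
      conf <- data.frame(element = elements, x = ab[, 1], y = ab[, 2],
                         z = ab[, 3], stringsAsFactors = FALSE)
    }
    hdr <- ChemmineR::header(sdf)
    id <- trimws(hdr[["Molecule_Name"]] %||% "")
    if (!nzchar(id)) id <- paste0("ligand_", i)
    out[[i]] <- ligand(id, conformer = conf)
    out[[i]]$sdf <- sdf  # keep connectivity for descriptor work
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

smiles_to_sdf <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("SMILES parsing requires the ChemmineOB package", call. = FALSE)
  # ChemmineR warns on bond-free records (single heavy atoms); atom
  # counts are validated by the callers instead
  suppressWarnings(ChemmineR::smiles2sdf(smiles))
}
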