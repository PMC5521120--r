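# Bundled amino-acid property tables used for residue encoding.
#
# Values are stored in the alphabet order of aa_alphabet():
#   A C D E F G H I K L M N P Q R S T V W Y
#
# Sources are recorded per table; dHf, L19 and Xi derive from an inaccessible
# publication and are shipped as clearly-labelled synthetic stand-in tables
# (fixed arbitrary values in a plausible range) so that the full 16-index
# encoding surface is available.

aa_table <- function(name, values, units, source) {
  v <- stats::setNames(values, aa_alphabet())
  stopifnot(length(v) == 20L, all(is.finite(v)))
  structure(list(name = name, values = v, units = units, source = source),
            class = "aa_index_table")
}

#' @export
print.aa_index_table <- function(x, ...) {
  cat(sprintf("Amino-acid index table '%s' (%s)\n", x$name, x$units))
  cat("  source:", x$source, "\n")
  print(round(x$values, 4))
  invisible(x)
}

# total water-accessible surface area of residue X in Gly-X-Gly, A^2
.aa_asa_total <- c(113, 140, 151, 183, 218,  85, 194, 182, 211, 180,
                   204, 158, 143, 189, 241, 122, 146, 160, 259, 229)

.build_bundled_indices <- function() {
  hp <- c(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
          1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3)
  list(
    HP = aa_table("HP", hp, "dimensionless",
                  "Kyte & Doolittle hydropathy, AAindex KYTJ820101"),
    Mw = aa_table("Mw",
      c(89.09, 121.16, 133.10, 147.13, 165.19, 75.07, 155.15, 131.17,
        146.19, 131.17, 149.21, 132.12, 115.13, 146.15, 174.20, 105.09,
        119.12, 117.15, 204.23, 181.19),
      "g/mol", "free amino-acid molecular mass (standard table)"),
    IP = aa_table("IP",
      c(6.00, 5.05, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02, 9.74, 5.98,
        5.74, 5.41, 6.30, 5.65, 10.76, 5.68, 5.66, 5.96, 5.89, 5.66),
      "pH", "isoelectric point, AAindex ZIMJ680104"),
    z1 = aa_table("z1",
      c(0.07, 0.71, 3.64, 3.08, -4.92, 2.23, 2.41, -4.44, 2.84, -4.19,
        -2.49, 3.22, -1.22, 2.18, 2.88, 1.96, 0.92, -2.69, -4.75, -1.39),
      "dimensionless", "Hellberg principal property z1 (hydrophilicity)"),
    z2 = aa_table("z2",
      c(-1.73, -0.97, 1.13, 0.39, 1.30, -5.36, 1.74, -1.68, 1.41, -1.03,
        -0.27, 1.45, 0.88, 0.53, 2.52, -1.63, -2.09, -2.53, 3.65, 2.32),
      "dimensionless", "Hellberg principal property z2 (steric bulk)"),
    z3 = aa_table("z3",
      c(0.09, 4.13, 2.36, -0.07, 0.45, 0.30, 1.11, -1.03, -3.14, -0.98,
        -0.41, 0.84, 2.23, -1.14, -3.44, 0.57, -1.40, -1.29, 0.85, 0.01),
      "dimensionless", "Hellberg principal property z3 (electronic)"),
    pa = aa_table("pa",
      c(1.29, 1.11, 1.04, 1.44, 1.07, 0.56, 1.22, 0.97, 1.23, 1.30,
        1.47, 0.90, 0.52, 1.27, 0.96, 0.82, 0.82, 0.91, 0.99, 0.72),
      "propensity", "Levitt alpha-helix probability, AAindex LEVM780101"),
    pb = aa_table("pb",
      c(0.90, 0.74, 0.72, 0.75, 1.32, 0.92, 1.08, 1.45, 0.77, 1.02,
        0.97, 0.76, 0.64, 0.80, 0.99, 0.95, 1.21, 1.49, 1.14, 1.25),
      "propensity", "Levitt beta-sheet probability, AAindex LEVM780102"),
    pt = aa_table("pt",
      c(0.77, 0.81, 1.41, 0.99, 0.59, 1.64, 0.68, 0.51, 0.96, 0.58,
        0.41, 1.28, 1.91, 0.98, 0.88, 1.32, 1.04, 0.47, 0.76, 1.05),
      "propensity", "Levitt reverse-turn probability, AAindex LEVM780103"),
    ECI = aa_table("ECI",
      c(0.05, 0.15, 1.25, 1.31, 0.14, 0.02, 0.56, 0.09, 0.53, 0.10,
        0.34, 1.31, 0.16, 1.36, 1.69, 0.56, 0.65, 0.07, 1.08, 0.72),
      "e", "electronic charge index, Collantes & Dunn 1995"),
    ISA = aa_table("ISA",
      c(62.90, 78.51, 18.46, 19.38, 189.42, 19.93, 87.38, 149.77, 102.78,
        154.35, 132.22, 17.87, 122.35, 19.53, 52.98, 19.75, 59.44, 120.91,
        179.16, 132.16),
      "A^2", "isotropic surface area, Collantes & Dunn 1995"),
    Ap = aa_table("Ap",
      c(25, 19, 58, 77, 24, 23, 43, 23, 110, 23,
        31, 69, 16, 91, 144, 44, 46, 23, 27, 43),
      "A^2", "polar water-accessible area (Gly-X-Gly), Miller et al. 1987"),
    dGsU = aa_table("dGsU", hp * .aa_asa_total,
      "dimensionless * A^2",
      paste("computed: Kyte-Doolittle hydropathy x total accessible surface",
            "area (Miller et al. 1987, Gly-X-Gly)")),
    dHf = aa_table("dHf",
      c(-124.9, -118.3, -189.7, -195.2, -102.4, -126.8, -141.6, -113.7,
        -158.9, -115.2, -131.4, -176.3, -133.8, -181.5, -202.6, -162.1,
        -157.4, -111.9, -98.7, -121.3),
      "kcal/mol",
      "SYNTHETIC stand-in for the nonapeptide formation-enthalpy scale (original source unavailable)"),
    L19 = aa_table("L19",
      c(0.42, 0.55, 0.37, 0.36, 0.68, 0.30, 0.49, 0.66, 0.33, 0.65,
        0.58, 0.35, 0.28, 0.38, 0.34, 0.39, 0.44, 0.62, 0.71, 0.60),
      "dimensionless",
      "SYNTHETIC stand-in for the L1-9 residue-compatibility scale (original source unavailable)"),
    Xi = aa_table("Xi",
      c(0.18, 0.44, -0.32, -0.35, 0.52, -0.12, 0.22, 0.49, -0.41, 0.47,
        0.39, -0.28, -0.22, -0.25, -0.45, -0.08, 0.05, 0.43, 0.55, 0.36),
      "dimensionless",
      "SYNTHETIC stand-in for the Xi residue-compatibility scale (original source unavailable)")
  )
}

# registry: bundled tables plus session-registered custom tables
.aa_registry <- new.env(parent = emptyenv())

aa_registry <- function() {
  if (is.null(.aa_registry$tables)) .aa_registry$tables <- .build_bundled_indices()
  .aa_registry$tables
}

#' List registered amino-acid index codes
#'
#' @return Character vector of index codes usable with [get_index()].
#' @export
list_indices <- function() names(aa_registry())

#' Retrieve an amino-acid index table by code
#'
#' Sixteen property tables ship with the package (hydropathy `HP`, molecular
#' mass `Mw`, isoelectric point `IP`, principal-property z-scales `z1`-`z3`,
#' Levitt helix/sheet/turn propensities `pa`/`pb`/`pt`, electronic charge index
#' `ECI`, isotropic surface area `ISA`, polar area `Ap`, surface free energy
#' `dGsU`, and the stand-in scales `dHf`, `L19`, `Xi`); custom tables can be
#' added with [load_custom_table()] and shadow bundled ones.
#'
#' @param name Index code, e.g. `"HP"`.
#' @return An `aa_index_table`: list with `name`, `values` (named 20-vector),
#'   `units`, `source`.
#' @export
#' @examples
#' get_index("HP")$values[["I"]] # 4.5
get_index <- function(name) {
  reg <- aa_registry()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown index '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  }
  reg[[name]]
}

#' Register a custom amino-acid index table from a file
#'
#' File format: first line `#name <code>`, then 20 lines `<residue>\t<value>`
#' covering every standard residue exactly once.
#'
#' @param path Path to the table file.
#' @return The registered `aa_index_table`, invisibly.
#' @export
load_custom_table <- function(path) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !grepl("^#name\\s+\\S+", lines[1L])) {
    stop("first line must be '#name <code>'", call. = FALSE)
  }
  code <- sub("^#name\\s+(\\S+).*$", "\\1", lines[1L])
  body <- strsplit(lines[-1L], "[\t ]+")
  res <- vapply(body, `[`, "", 1L)
  val <- suppressWarnings(as.numeric(vapply(body, `[`, "", 2L)))
  if (anyNA(val)) {
    stop("non-numeric value for residue(s): ",
         paste(res[is.na(val)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(res)) {
    stop("duplicate residue(s): ",
         paste(unique(res[duplicated(res)]), collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(aa_alphabet(), res)
  if (length(miss)) {
    stop("missing residue(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(res, aa_alphabet())
  if (length(extra)) {
    stop("unknown residue(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  tab <- aa_table(code, stats::setNames(val, res)[aa_alphabet()],
                  units = "custom", source = paste("custom table from", path))
  reg <- aa_registry()
  reg[[code]] <- tab
  .aa_registry$tables <- reg
  invisible(tab)
}

#' Register an in-memory custom index table
#'
#' @param name Index code.
#' @param values Named numeric 20-vector over the standard residues.
#' @param units,source Metadata strings.
#' @return The registered `aa_index_table`, invisibly.
#' @export
register_index <- function(name, values, units = "custom", source = "user") {
  stopifnot(setequal(names(values), aa_alphabet()))
  tab <- aa_table(name, values[aa_alphabet()], units, source)
  reg <- aa_registry()
  reg[[name]] <- tab
  .aa_registry$tables <- reg
  invisible(tab)
}
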