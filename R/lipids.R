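#' Default lipid species registry
#'
#' Head-group charges (elementary charges at pH 7.5), mean molecular areas
#' (\eqn{\mathrm{\AA}^2}) and a primary-phosphate flag for the phospholipids
#' handled by the package. Phosphatidic acids (POPA, DPhPA, DMPA, DOPA, BrPOPA)
#' carry an unesterified (primary) phosphate and are treated as net -1 at
#' pH 7.5; phosphodiester head-groups (PC, PE, PG, PS, PI, sphingomyelin) are
#' not primary phosphates. All areas default to 80 A^2, the mean area of a
#' DPhPC molecule. Entries flagged \code{low_confidence} (DOPP, PIP, the
#' phosphomethanol/phosphoethanol esters) have protonation states that are not
#' settled at pH 7.5; override them with \code{\link{read_lipid_registry}} if
#' needed.
#'
#' @return A data.frame with columns \code{name}, \code{charge}, \code{area},
#'   \code{primary_phosphate}, \code{low_confidence}.
#' @export
#' @examples
#' default_lipid_registry()
default_lipid_registry <- function() {
  path <- system.file("extdata", "lipid_registry.csv", package = "kvlipid",
                      mustWork = TRUE)
  read_lipid_registry(path)
}

#' Read a lipid registry table from CSV or YAML
#'
#' A registry is a table of lipid species properties: signed head-group charge,
#' area per molecule and whether the head-group is a primary (unesterified)
#' phosphate. Users can supply their own table to override the packaged
#' defaults, e.g. to model PA as -2.
#'
#' @param path CSV file (columns \code{name}, \code{charge}, \code{area},
#'   \code{primary_phosphate}, optionally \code{low_confidence}) or a YAML file
#'   holding a list of records with the same fields.
#' @return A registry data.frame.
#' @export
read_lipid_registry <- function(path) {
  if (!file.exists(path)) stop("lipid registry file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    recs <- yaml::read_yaml(path)
    reg <- do.call(rbind, lapply(recs, function(r) {
      data.frame(name = r$name, charge = as.numeric(r$charge),
                 area = as.numeric(r$area),
                 primary_phosphate = isTRUE(r$primary_phosphate),
                 low_confidence = isTRUE(r$low_confidence),
                 stringsAsFactors = FALSE)
    }))
  } else {
    reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("name", "charge", "area", "primary_phosphate")
  missing <- setdiff(required, names(reg))
  if (length(missing))
    stop("lipid registry is missing columns: ", paste(missing, collapse = ", "))
  if (is.null(reg$low_confidence)) reg$low_confidence <- FALSE
  if (any(reg$area <= 0)) stop("lipid areas must be positive")
  if (anyDuplicated(reg$name)) stop("duplicate lipid names in registry")
  reg
}

.registry_lookup <- function(species, registry) {
  idx <- match(species, registry$name)
  if (anyNA(idx))
    stop("unknown lipid species: ",
         paste(species[is.na(idx)], collapse = ", "))
  registry[idx, , drop = FALSE]
}

#' Leaflet lipid composition
#'
#' A named vector of mole fractions describing one monolayer of a bilayer.
#' Fractions must be nonnegative and sum to 1 (tolerance 1e-9).
#'
#' @param fractions Named numeric vector of mole fractions, names are lipid
#'   species.
#' @param normalize If TRUE, divide by the sum instead of requiring it to be 1
#'   (convenient for mole-ratio input).
#' @return A \code{leaflet_composition} object.
#' @export
#' @examples
#' leaflet_composition(c(DPhPC = 0.75, POPA = 0.25))
#' leaflet_composition(c(DPhPC = 3, POPA = 1), normalize = TRUE) # "3:1" mix
leaflet_composition <- function(fractions, normalize = FALSE) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("mole fractions must be a named vector of lipid species")
  fractions <- vapply(split(unname(fractions), names(fractions)), sum,
                      numeric(1))
  if (any(fractions < 0)) stop("mole fractions must be nonnegative")
  total <- sum(fractions)
  if (normalize) {
    if (total <= 0) stop("cannot normalize an all-zero composition")
    fractions <- fractions / total
  } else if (abs(total - 1) > 1e-9) {
    stop("mole fractions must sum to 1 (got ", format(total), "); ",
         "use normalize = TRUE for mole-ratio input")
  }
  structure(fractions, class = "leaflet_composition")
}

#' @export
print.leaflet_composition <- function(x, ...) {
  cat("<leaflet composition>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Bilayer specification
#'
#' Per-leaflet lipid compositions plus electrolyte concentration and
#' temperature. \code{inner} is the physiologically intracellular leaflet for
#' an outside-out channel (the \emph{cis}-chamber side in the recording
#' convention); \code{outer} faces the extracellular solution (\emph{trans}).
#'
#' @param inner,outer \code{\link{leaflet_composition}} objects (or named
#'   fraction vectors, coerced).
#' @param electrolyte_molar Monovalent electrolyte concentration in M
#'   (default 0.15 M KCl, the post-equilibration recording condition).
#' @param temperature Kelvin (default 298).
#' @return A \code{bilayer_spec} object.
#' @export
#' @examples
#' bilayer_spec(inner = c(DPhPC = 1), outer = c(DPhPC = 1))
bilayer_spec <- function(inner, outer, electrolyte_molar = 0.15,
                         temperature = 298) {
  if (!inherits(inner, "leaflet_composition"))
    inner <- leaflet_composition(inner)
  if (!inherits(outer, "leaflet_composition"))
    outer <- leaflet_composition(outer)
  stopifnot(is.numeric(electrolyte_molar), length(electrolyte_molar) == 1)
  if (electrolyte_molar <= 0) stop("electrolyte_molar must be > 0")
  stopifnot(is.numeric(temperature), temperature > 0)
  structure(list(inner = inner, outer = outer,
                 electrolyte_molar = electrolyte_molar,
                 temperature = temperature),
            class = "bilayer_spec")
}

#' @export
print.bilayer_spec <- function(x, ...) {
  fmt <- function(comp) paste(sprintf("%s %.3f", names(comp), unclass(comp)),
                              collapse = ", ")
  cat("<bilayer spec>\n")
  cat("  inner (intracellular): ", fmt(x$inner), "\n", sep = "")
  cat("  outer (extracellular): ", fmt(x$outer), "\n", sep = "")
  cat(sprintf("  electrolyte %.3g M, temperature %g K\n",
              x$electrolyte_molar, x$temperature))
  invisible(x)
}

# Map a chamber token to a bilayer leaflet name. cis = chamber where channels
# are added = intracellular-facing leaflet of outside-out channels.
.resolve_side <- function(side) {
  switch(match.arg(side, c("inner", "outer", "cis", "trans")),
         inner = "inner", cis = "inner",
         outer = "outer", trans = "outer")
}
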