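# Pore electrostatic fingerprint from residue lists: the formal-charge
# ladder along the pore and the net pore charge. Charged pore-lining
# residues are contributed in symmetric multiples (a tetrameric pore
# scaffold contributes each residue four times, including residues donated
# by the interlocking loops of neighbouring subunits); residues that are
# persistently shielded by salt-bridge partners are excluded from the sum.

#' Formal charge of a residue type
#'
#' Arg/Lys +1, Asp/Glu -1, His (and everything else) 0; histidine is treated
#' as neutral at physiological pH. Unknown names yield 0 with a warning.
#'
#' @param res_name 3-letter residue name (vectorised).
#' @return integer vector of formal charges.
#' @export
formal_charge <- function(res_name) {
  rn <- toupper(trimws(res_name))
  known <- c(ARG = 1L, LYS = 1L, ASP = -1L, GLU = -1L, HIS = 0L,
             ALA = 0L, ASN = 0L, CYS = 0L, GLN = 0L, GLY = 0L, ILE = 0L,
             LEU = 0L, MET = 0L, PHE = 0L, PRO = 0L, SER = 0L, THR = 0L,
             TRP = 0L, TYR = 0L, VAL = 0L)
  out <- known[rn]
  if (anyNA(out)) {
    warning("unknown residue name(s): ",
            paste(unique(rn[is.na(out)]), collapse = ", "),
            "; treated as neutral", call. = FALSE)
    out[is.na(out)] <- 0L
  }
  unname(out)
}

# "K29" -> list(res_name = "LYS", res_num = 29)
.parse_residue_label <- function(label) {
  aa1to3 <- setNames(names(.aa3to1), unname(.aa3to1))
  code <- sub("^([A-Za-z]+)([0-9]+)$", "\\1", label)
  num <- as.integer(sub("^([A-Za-z]+)([0-9]+)$", "\\2", label))
  res3 <- if (nchar(code) == 1L) aa1to3[toupper(code)] else toupper(code)
  if (is.na(res3)) stop("cannot parse residue label: ", label)
  list(res_name = unname(res3), res_num = num)
}

#' Pore-lining residue specification
#'
#' The per-subunit list of pore-lining residues, the multiplicity with which
#' each appears around the pore (default 4, the tetrameric scaffold), and
#' the subset excluded from the net-charge sum because it is persistently
#' shielded.
#'
#' @param residues character vector of residue labels, one-letter code plus
#'   number (e.g. `"K29"`) or 3-letter code plus number (`"LYS29"`).
#' @param multiplicity copies of each residue around the pore (default 4).
#' @param shielded subset of `residues` excluded from the sum.
#' @param label optional name for the spec (e.g. the claudin isoform).
#' @return Object of class `pore_lining_spec`.
#' @export
pore_lining_spec <- function(residues, multiplicity = 4L, shielded = character(0),
                             label = "") {
  stopifnot(multiplicity >= 1L)
  if (!all(shielded %in% residues))
    stop("shielded residues must be a subset of the listed residues")
  parsed <- lapply(residues, .parse_residue_label)
  structure(list(
    residues = data.frame(
      label = residues,
      res_name = vapply(parsed, `[[`, character(1), "res_name"),
      res_num = vapply(parsed, `[[`, integer(1), "res_num"),
      multiplicity = rep(as.integer(multiplicity), length(residues)),
      shielded = residues %in% shielded),
    label = label),
    class = "pore_lining_spec")
}

#' Net pore charge
#'
#' Sum over non-shielded listed residues of formal charge x multiplicity.
#'
#' @param spec a [pore_lining_spec()].
#' @return integer net charge (elementary charges).
#' @export
pore_net_charge <- function(spec) {
  stopifnot(inherits(spec, "pore_lining_spec"))
  r <- spec$residues
  if (nrow(r) == 0L) return(0L)
  keep <- !r$shielded
  sum(formal_charge(r$res_name[keep]) * r$multiplicity[keep])
}

#' Formal-charge ladder of a pore lining
#'
#' @param spec a [pore_lining_spec()].
#' @return data frame `residue`, `charge`, `multiplicity`, `shielded`,
#'   `contribution`.
#' @export
charge_ladder <- function(spec) {
  r <- spec$residues
  ch <- formal_charge(r$res_name)
  data.frame(residue = r$label, charge = ch, multiplicity = r$multiplicity,
             shielded = r$shielded,
             contribution = ifelse(r$shielded, 0L, ch * r$multiplicity))
}

#' Built-in pore-lining specs for the claudin-10 isoforms
#'
#' The charged and polar residues lining the claudin-10a and -10b pores
#' (per-subunit numbering), each contributed four times around the
#' tetrameric pore scaffold, with the persistently shielded
#' lysine/glutamate pair excluded from the net-charge sum. These specs
#' reproduce the isoforms' opposite pore net charges (+8 anion-attracting
#' for claudin-10a, -12 cation-attracting for claudin-10b).
#'
#' @param isoform `"CLDN10a"` or `"CLDN10b"`.
#' @return A [pore_lining_spec()].
#' @export
cldn10_pore_lining <- function(isoform = c("CLDN10a", "CLDN10b")) {
  isoform <- match.arg(isoform)
  if (isoform == "CLDN10a")
    pore_lining_spec(
      residues = c("K29", "R33", "N54", "H60", "R62", "K69",
                   "E143", "D146", "K139", "E151", "K153", "E155"),
      shielded = c("K153", "E155"), label = "CLDN10a")
  else
    pore_lining_spec(
      residues = c("K31", "D36", "D56", "N62", "K64", "D73",
                   "E145", "D148", "K141", "E153", "K155", "E157"),
      shielded = c("K155", "E157"), label = "CLDN10b")
}

#' Write a charge fingerprint to JSON
#' @param spec a [pore_lining_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_charge_fingerprint <- function(spec, path) {
  jsonlite::write_json(
    list(label = spec$label, net_charge = pore_net_charge(spec),
         ladder = charge_ladder(spec)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
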