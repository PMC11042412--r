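# Monoisotopic mass arithmetic for residues, peptides and b/y-family
# product ions.  All masses are monoisotopic and in Daltons.

#' Physical constants (monoisotopic, Da)
#'
#' Proton, water and ammonia monoisotopic masses used throughout the
#' package's fragment-ion arithmetic.
#' @name mass-constants
#' @keywords internal
NULL

PROTON_MASS <- 1.007276
H2O_MASS    <- 18.010565
NH3_MASS    <- 17.026549

# Monoisotopic residue masses; C carries the fixed carbamidomethyl
# modification (+57.02146) as in standard alkylated samples.
.FULL_RESIDUES <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,  V = 99.06841,
  T = 101.04768, C = 160.03065, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Reduced alphabet for fast, isobaric-free fixtures: pairwise residue-mass
# gaps all exceed 1 Da, so mass evidence identifies residues unambiguously.
.REDUCED_SYMBOLS <- c("G", "A", "S", "P", "V")

START_TOKEN <- "<start>"
STOP_TOKEN  <- "<stop>"
PAD_TOKEN   <- "<pad>"

#' Build a residue table / decoding vocabulary
#'
#' The residue table maps residue symbols to monoisotopic masses and fixes
#' the vocabulary slot layout used by the model and the product-ion array:
#' residues first, then the massless special tokens (start, stop, pad),
#' then zero or more massless reserved slots so that the slot count can be
#' held at a configured value (default 26 for the full 20-residue
#' alphabet).
#'
#' Cysteine in the full table is carbamidomethylated (+57.02146 Da), the
#' standard fixed modification for alkylated samples; no variable
#' modifications are supported.
#'
#' @param alphabet `"full"` (20 canonical residues, C modified) or
#'   `"reduced"` (G, A, S, P, V; pairwise mass gaps > 1 Da), or a named
#'   numeric vector of residue masses for custom alphabets.
#' @param n_slots total vocabulary slot count; must be at least
#'   `n residues + 3`.  Default 26 for the full alphabet, residues + 3
#'   otherwise.
#' @return An object of class `residue_table` with fields `symbols`
#'   (length `n_slots`), `mass` (named, 0 for massless slots),
#'   `is_residue`, and the special-token ids `start_id`, `stop_id`,
#'   `pad_id`.
#' @export
#' @examples
#' tab <- residue_table()
#' residue_mass(tab, "G")
#' peptide_mass(tab, "PEPTIDE")
residue_table <- function(alphabet = "full", n_slots = NULL) {
  if (is.character(alphabet) && length(alphabet) == 1L) {
    res <- switch(alphabet,
      full    = .FULL_RESIDUES,
      reduced = .FULL_RESIDUES[.REDUCED_SYMBOLS],
      stop("unknown alphabet preset: ", alphabet)
    )
  } else if (is.numeric(alphabet) && !is.null(names(alphabet))) {
    res <- alphabet
  } else {
    stop("alphabet must be a preset name or a named numeric vector")
  }
  if (any(res <= 0)) stop("residue masses must be strictly positive")
  nr <- length(res)
  if (is.null(n_slots)) {
    n_slots <- if (identical(alphabet, "full")) 26L else nr + 3L
  }
  n_slots <- as.integer(n_slots)
  if (n_slots < nr + 3L)
    stop("n_slots must accommodate all residues plus 3 special tokens")
  n_reserved <- n_slots - nr - 3L
  symbols <- c(names(res), START_TOKEN, STOP_TOKEN, PAD_TOKEN,
               if (n_reserved > 0L) sprintf("<rsv%d>", seq_len(n_reserved)))
  mass <- c(unname(res), rep(0, n_slots - nr))
  names(mass) <- symbols
  structure(
    list(
      symbols    = symbols,
      mass       = mass,
      is_residue = c(rep(TRUE, nr), rep(FALSE, n_slots - nr)),
      n_slots    = n_slots,
      start_id   = nr + 1L,
      stop_id    = nr + 2L,
      pad_id     = nr + 3L
    ),
    class = "residue_table"
  )
}

#' @export
print.residue_table <- function(x, ...) {
  cat(sprintf("residue_table: %d residues, %d slots\n",
              sum(x$is_residue), x$n_slots))
  invisible(x)
}

#' Monoisotopic mass of one residue
#'
#' @param table a [residue_table()]
#' @param symbol residue symbol (or special token)
#' @return mass in Da; special tokens are massless (0)
#' @export
residue_mass <- function(table, symbol) {
  stopifnot(inherits(table, "residue_table"))
  m <- table$mass[symbol]
  if (anyNA(m)) {
    stop("unknown residue symbol(s): ",
         paste(symbol[is.na(m)], collapse = ", "))
  }
  unname(m)
}

#' Split a peptide string into residue symbols
#'
#' Peptides are written with one character per residue (C is always the
#' carbamidomethylated form).  A character vector of symbols is returned
#' unchanged after validation.
#'
#' @inheritParams residue_mass
#' @param peptide peptide string or character vector of residue symbols
#' @return character vector of residue symbols (length 0 for "")
#' @export
peptide_symbols <- function(table, peptide) {
  if (length(peptide) == 1L && (is.na(peptide) || nchar(peptide) != 1L)) {
    if (is.na(peptide) || identical(peptide, "")) return(character(0))
    peptide <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  }
  bad <- !(peptide %in% table$symbols[table$is_residue])
  if (any(bad))
    stop("unknown residue symbol(s): ", paste(unique(peptide[bad]), collapse = ", "))
  peptide
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water (18.010565 Da).  The empty peptide
#' degenerates to the mass of water.
#'
#' @inheritParams peptide_symbols
#' @return neutral mass in Da
#' @export
peptide_mass <- function(table, peptide) {
  syms <- peptide_symbols(table, peptide)
  sum(residue_mass(table, syms)) + H2O_MASS
}

#' The eight product-ion types
#'
#' b, y, their doubly-charged forms, and their water/ammonia neutral-loss
#' variants.  `series` says whether the ion mass derives from the prefix
#' (b family) or suffix (y family) of the cleaved peptide.
#'
#' @return data.frame with columns `name`, `series`, `charge`, `loss`
#' @export
ion_types <- function() {
  data.frame(
    name   = c("b", "y", "b(2+)", "y(2+)", "b-H2O", "y-H2O", "b-NH3", "y-NH3"),
    series = c("prefix", "suffix", "prefix", "suffix",
               "prefix", "suffix", "prefix", "suffix"),
    charge = c(1L, 1L, 2L, 2L, 1L, 1L, 1L, 1L),
    loss   = c(0, 0, 0, 0, H2O_MASS, H2O_MASS, NH3_MASS, NH3_MASS),
    stringsAsFactors = FALSE
  )
}

#' Theoretical product-ion m/z
#'
#' For a cleavage with cumulative prefix residue mass `prefix_mass` of a
#' peptide whose residues sum to `total_mass` (water excluded), the
#' prefix-series ions are `(prefix - loss + z * proton) / z` and the
#' suffix-series ions are `(total - prefix + H2O - loss + z * proton) / z`.
#' Singly-charged b and y ions of complementary cuts therefore sum to the
#' neutral peptide mass plus two proton masses.
#'
#' @param prefix_mass cumulative residue mass of the prefix, Da
#' @param total_mass sum of all residue masses (no water), Da
#' @param ion one row of [ion_types()], or an ion name
#' @return m/z value(s); vectorized over `prefix_mass`
#' @export
fragment_mz <- function(prefix_mass, total_mass, ion) {
  if (is.character(ion)) {
    it <- ion_types()
    ion <- it[match(ion, it$name), ]
    if (anyNA(ion$name)) stop("unknown ion type")
  }
  stopifnot(all(prefix_mass >= -1e-9), all(prefix_mass <= total_mass + 1e-9))
  z <- ion$charge
  if (ion$series == "prefix") {
    (prefix_mass - ion$loss + z * PROTON_MASS) / z
  } else {
    (total_mass - prefix_mass + H2O_MASS - ion$loss + z * PROTON_MASS) / z
  }
}

#' Serialize / load a residue table
#'
#' Plain-text `symbol<TAB>mass` lines so alternative alphabets (e.g. the
#' simulator's reduced alphabet) can be stored and reloaded.  Special and
#' reserved slots are included, so the slot layout round-trips exactly.
#'
#' @inheritParams residue_mass
#' @param path file path
#' @return `read_residue_table` returns a [residue_table()]
#' @export
write_residue_table <- function(table, path) {
  stopifnot(inherits(table, "residue_table"))
  writeLines(sprintf("%s\t%.6f", table$symbols, table$mass), path)
  invisible(path)
}

#' @rdname write_residue_table
#' @export
read_residue_table <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  syms <- vapply(parts, `[`, "", 1L)
  mass <- as.numeric(vapply(parts, `[`, "", 2L))
  is_special <- grepl("^<", syms)
  res <- mass[!is_special]
  names(res) <- syms[!is_special]
  residue_table(res, n_slots = length(syms))
}
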