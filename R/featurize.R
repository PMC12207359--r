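# Reaction featurization.
#
# A reaction is represented by a fixed 1544-dimensional vector:
# three 512-bit circular fingerprints (olefin, ligand, solvent),
# a 3-slot metal one-hot (Ir, Rh, Ru), a 2-slot additive one-hot
# (absent, present) and three reaction-condition scalars
# (temperature / degC, pressure / bar, catalyst loading / mol%).

DKMETA_METALS <- c("Ir", "Rh", "Ru")

REACTION_COLUMNS <- c("reaction_id", "olefin_smiles", "ligand_smiles",
                      "solvent_smiles", "metal", "additive",
                      "temperature_c", "pressure_bar", "loading_molpct",
                      "ee", "year")

# Memoized per-session canonicalization cache (SMILES parsing through
# OpenBabel dominates featurization cost otherwise).
.smiles_cache <- new.env(parent = emptyenv())

canonicalize_one <- function(s) {
  hit <- get0(s, envir = .smiles_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = s)),
    error = function(e) "")
  out <- strsplit(out, "[\t\n ]")[[1]][1]
  if (is.na(out)) out <- ""
  assign(s, out, envir = .smiles_cache)
  out
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form so that different
#' spellings of the same molecule map to identical fingerprints.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  out <- vapply(smiles, canonicalize_one, character(1), USE.NAMES = FALSE)
  bad <- smiles[!nzchar(out)]
  if (length(bad)) {
    stop("unparseable SMILES: ", paste(sQuote(unique(bad)), collapse = ", "),
         call. = FALSE)
  }
  out
}

# Raw OpenBabel fingerprints for a vector of (already validated,
# canonical) SMILES; one row per molecule.
ob_fingerprints <- function(can, type) {
  mols <- ChemmineOB::forEachMol("SMILES", paste0(can, collapse = "\n"),
                                 identity)
  f <- suppressWarnings(ChemmineOB::fingerprint_OB(mols, type))
  if (!is.matrix(f)) f <- matrix(f, nrow = 1)
  if (nrow(f) != length(can)) {
    stop("fingerprinting failed for some molecules", call. = FALSE)
  }
  (f != 0) * 1L
}

# Fold a wide binary fingerprint matrix to n_bits columns by OR-ing
# bit i into slot (i mod n_bits).
fold_bits <- function(fp, n_bits) {
  slot <- (seq_len(ncol(fp)) - 1L) %% n_bits + 1L
  out <- matrix(0L, nrow(fp), n_bits)
  for (s in unique(slot)) {
    out[, s] <- as.integer(rowSums(fp[, slot == s, drop = FALSE]) > 0)
  }
  out
}

#' Circular (Morgan-style) fingerprint
#'
#' Extended-connectivity circular fingerprint of the given radius
#' (computed by OpenBabel as ECFP\code{2*radius}), folded to a fixed
#' number of bits.  Deterministic for a fixed molecule and invariant to
#' the SMILES spelling.
#'
#' @param smiles character vector of SMILES.
#' @param n_bits folded fingerprint length (default 512).
#' @param radius circular neighbourhood radius in bonds (default 2).
#' @return For one SMILES, a binary vector of length `n_bits`; otherwise
#'   a binary matrix with one row per molecule.
#' @export
morgan_fingerprint <- function(smiles, n_bits = 512, radius = 2) {
  stopifnot(n_bits >= 1, radius %in% 0:5)
  can <- canonical_smiles(smiles)
  uc <- unique(can)
  fp <- ob_fingerprints(uc, paste0("ECFP", 2L * radius))
  out <- fold_bits(fp, n_bits)[match(can, uc), , drop = FALSE]
  if (length(smiles) == 1) out[1, ] else out
}

#' MACCS structural keys
#'
#' The 166-bit dictionary-based structural fingerprint used for
#' substrate clustering (OpenBabel MACCS definitions; the padded
#' 256-bit register is truncated to the canonical 166 keys).
#'
#' @param smiles character vector of SMILES.
#' @return Binary vector of length 166 (or a matrix, one row per SMILES).
#' @export
maccs_fingerprint <- function(smiles) {
  can <- canonical_smiles(smiles)
  uc <- unique(can)
  fp <- ob_fingerprints(uc, "MACCS")[, 1:166, drop = FALSE]
  out <- fp[match(can, uc), , drop = FALSE]
  if (length(smiles) == 1) out[1, ] else out
}

#' Binarize percent enantiomeric excess
#'
#' Reactions strictly above the threshold are labelled 1 (highly
#' enantioselective); values equal to the threshold fall in the low
#' class, giving a single unambiguous boundary rule.
#'
#' @param ee numeric percent-ee values in \[0, 100\].
#' @param threshold classification threshold (default 80; 85 and 90 are
#'   the supported sensitivity settings).
#' @return integer vector of 0/1 labels.
#' @export
binarize_ee <- function(ee, threshold = 80) {
  stopifnot(is.numeric(ee), threshold >= 0, threshold <= 100)
  if (any(!is.finite(ee) | ee < 0 | ee > 100)) {
    stop("ee values must lie in [0, 100]", call. = FALSE)
  }
  as.integer(ee > threshold)
}

#' Fit a z-score scaler for the reaction-condition columns
#'
#' Means and standard deviations of temperature, pressure and catalyst
#' loading, to be estimated on training data only and applied everywhere
#' (unscaled degC/bar magnitudes would otherwise dominate the binary
#' fingerprint block in distance-based kernels).
#'
#' @param records reaction data frame (see [read_reactions()] schema).
#' @return object of class `condition_scaler`.
#' @export
fit_condition_scaler <- function(records) {
  cols <- c("temperature_c", "pressure_bar", "loading_molpct")
  stopifnot(all(cols %in% names(records)))
  mu <- vapply(records[cols], mean, 1, na.rm = TRUE)
  sd <- vapply(records[cols], stats::sd, 1, na.rm = TRUE)
  sd[!is.finite(sd) | sd == 0] <- 1
  structure(list(mean = mu, sd = sd), class = "condition_scaler")
}

apply_scaler <- function(scaler, m) {
  if (is.null(scaler)) return(m)
  stopifnot(inherits(scaler, "condition_scaler"))
  sweep(sweep(m, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Encode reactions as fixed-length feature vectors
#'
#' Concatenates the three component fingerprints, the metal and additive
#' one-hot encodings and the (optionally scaled) reaction-condition
#' scalars into the full 1544-dimensional reaction representation.
#'
#' @param records reaction data frame with the [read_reactions()] schema.
#' @param scaler optional [fit_condition_scaler()] result (fit on
#'   training rows only); `NULL` leaves the condition scalars unscaled.
#' @param n_bits,radius fingerprint parameters (defaults give the
#'   512-bit, radius-2 standard layout).
#' @param impute optional named list of fallback values for missing
#'   condition entries (e.g. `list(pressure_bar = 1)`); without it,
#'   missing values are rejected.
#' @return numeric matrix with `3 * n_bits + 8` columns and an attribute
#'   `"layout"` describing the column blocks.
#' @export
encode_reactions <- function(records, scaler = NULL, n_bits = 512,
                             radius = 2, impute = NULL) {
  need <- setdiff(REACTION_COLUMNS, c("reaction_id", "ee", "year"))
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("missing reaction columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_metal <- setdiff(unique(records$metal), DKMETA_METALS)
  if (length(bad_metal)) {
    stop("unknown metal category: ", paste(sQuote(bad_metal), collapse = ", "),
         call. = FALSE)
  }
  cond <- as.matrix(records[c("temperature_c", "pressure_bar",
                              "loading_molpct")])
  storage.mode(cond) <- "double"
  if (anyNA(cond)) {
    for (col in colnames(cond)) {
      if (anyNA(cond[, col])) {
        if (is.null(impute[[col]])) {
          stop(sprintf("missing %s in rows %s (no imputation configured)",
                       col, paste(which(is.na(cond[, col])), collapse = ", ")),
               call. = FALSE)
        }
        cond[is.na(cond[, col]), col] <- impute[[col]]
      }
    }
  }
  cond <- apply_scaler(scaler, cond)
  fp_o <- rbind(morgan_fingerprint(records$olefin_smiles, n_bits, radius))
  fp_l <- rbind(morgan_fingerprint(records$ligand_smiles, n_bits, radius))
  fp_s <- rbind(morgan_fingerprint(records$solvent_smiles, n_bits, radius))
  metal <- matrix(0L, nrow(records), length(DKMETA_METALS),
                  dimnames = list(NULL, DKMETA_METALS))
  metal[cbind(seq_len(nrow(records)), match(records$metal, DKMETA_METALS))] <- 1L
  add <- as.logical(records$additive)
  if (anyNA(add)) stop("additive flag must be logical (TRUE/FALSE)")
  additive <- cbind(absent = as.integer(!add), present = as.integer(add))
  X <- cbind(fp_o, fp_l, fp_s, metal, additive, cond)
  dimnames(X) <- NULL
  attr(X, "layout") <- list(
    olefin_fp = c(1, n_bits),
    ligand_fp = c(n_bits + 1, 2 * n_bits),
    solvent_fp = c(2 * n_bits + 1, 3 * n_bits),
    metal_onehot = c(3 * n_bits + 1, 3 * n_bits + 3),
    additive_onehot = c(3 * n_bits + 4, 3 * n_bits + 5),
    conditions = c(3 * n_bits + 6, 3 * n_bits + 8))
  X
}

#' Encode a single reaction record
#'
#' @param record one-row reaction data frame.
#' @inheritParams encode_reactions
#' @return numeric feature vector (length `3 * n_bits + 8`).
#' @export
encode_reaction <- function(record, scaler = NULL, n_bits = 512,
                            radius = 2, impute = NULL) {
  stopifnot(NROW(record) == 1)
  drop(encode_reactions(record, scaler, n_bits, radius, impute)[1, ])
}
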