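#' Effect tables: class-wise metabolite fold-change designs
#'
#' An `EffectTable` stores, for each of the nine tissue classes, a log2
#' offset per metabolite relative to class 1 (normal squamous mucosa from
#' controls). Pairwise entries -- the signed log2 fold change of a metabolite
#' between two classes -- are differences of these offsets, which keeps every
#' pairwise direction mutually consistent by construction.
#'
#' @param offsets Numeric matrix, rows = class ids "1".."9", columns =
#'   metabolite names, entries = log2 offsets relative to class 1.
#' @return An object of class `EffectTable`.
#' @export
effect_table <- function(offsets) {
  offsets <- as.matrix(offsets)
  if (is.null(rownames(offsets)) || is.null(colnames(offsets))) {
    stop("offsets must have class-id rownames and metabolite colnames",
         call. = FALSE)
  }
  structure(list(offsets = offsets), class = "EffectTable")
}

#' Signed log2 fold change between two classes
#'
#' @param effects An `EffectTable`.
#' @param from,to Class ids (1-9). The entry is the log2 fold change going
#'   *from* `from` *to* `to`: positive means elevated in `to`.
#' @param metabolite Metabolite name, or NULL for the full named vector.
#' @return Numeric scalar (or named vector when `metabolite` is NULL).
#' @export
effect_entry <- function(effects, from, to, metabolite = NULL) {
  off <- effects$offsets
  from <- as.character(from); to <- as.character(to)
  if (!from %in% rownames(off) || !to %in% rownames(off)) {
    stop("unknown class id", call. = FALSE)
  }
  d <- off[to, ] - off[from, ]
  if (is.null(metabolite)) return(d)
  if (!metabolite %in% colnames(off)) {
    stop("unknown metabolite: ", metabolite, call. = FALSE)
  }
  unname(d[metabolite])
}

#' The default effect table
#'
#' Encodes the reported direction of every metabolite change between tissue
#' classes: the control-vs-EAC signature (myoinositol, inosine, hypoxanthine,
#' 3-hydroxybutyrate, glycerophosphocholine, phosphocholine and formate
#' elevated; glutamine, alanine, creatine, ADP and fumarate reduced), the
#' field-effect signature in histologically normal tissue of cancer patients
#' (3-hydroxybutyrate, succinate and formate strongly up; acetate,
#' glycerophosphocholine, ADP and lactate weakly up), the squamous-to-columnar
#' shift, the Barrett's-with-EAC signature (phosphocholine up; branched-chain
#' amino acids down) and the chemotherapy response (lactate up, formate down
#' in treated tissue). Magnitudes are simulation defaults: `strong` for
#' highly significant changes, `weak` for marginal ones.
#'
#' @param strong,weak Absolute log2 fold change assigned to strongly
#'   (default 1) and weakly (default 0.5) altered metabolites.
#' @return An `EffectTable`.
#' @export
default_effect_table <- function(strong = 1, weak = 0.5) {
  half <- weak / 2
  mets <- names(default_signature_names())
  off <- matrix(0, nrow = 9, ncol = length(mets),
                dimnames = list(as.character(1:9), mets))
  add <- function(cls, ...) {
    v <- c(...)
    off[as.character(cls), names(v)] <<- off[as.character(cls), names(v)] + v
  }
  # class 2: normal squamous tissue in Barrett's patients
  add(2, formate = weak, `3-hydroxybutyrate` = -weak)
  # class 3: normal squamous tissue in EAC patients (the field effect)
  add(3, `3-hydroxybutyrate` = strong, succinate = strong, formate = strong,
      acetate = weak, glycerophosphocholine = weak, ADP = weak,
      lactate = weak)
  # class 4: Barrett's tissue in Barrett's patients = class 2 + the
  # squamous-to-columnar signature
  add(4, formate = weak, `3-hydroxybutyrate` = -weak)
  add(4, `3-hydroxybutyrate` = strong, hypoxanthine = strong,
      phosphocholine = strong, glycerophosphocholine = strong,
      glutamine = -strong, alanine = -strong, glutamate = -half)
  # class 5: Barrett's tissue in EAC patients = class 4 pattern with
  # phosphocholine further elevated, branched-chain amino acids reduced,
  # and drifts toward the EAC profile (hypoxanthine/GPC rise 3 -> 5 -> 6,
  # creatine falls, propionate slightly up so it can fall again 5 -> 6)
  add(5, formate = weak, `3-hydroxybutyrate` = -weak)
  add(5, `3-hydroxybutyrate` = strong, hypoxanthine = 0.75 * strong,
      phosphocholine = strong + weak, glycerophosphocholine = 0.75 * strong,
      glutamine = -strong, alanine = -strong, glutamate = -half,
      leucine = -weak, isoleucine = -weak, valine = -weak,
      creatine = -weak, propionate = half)
  # class 6: EAC tissue prechemotherapy (the 12-metabolite cancer signature)
  add(6, myoinositol = strong, inosine = strong, hypoxanthine = strong,
      `3-hydroxybutyrate` = strong, glycerophosphocholine = strong,
      phosphocholine = strong, formate = strong,
      glutamine = -strong, alanine = -strong, creatine = -strong,
      ADP = -strong, fumarate = -strong)
  # class 7: class 3 + chemotherapy response in normal tissue
  off["7", ] <- off["3", ]
  add(7, valine = strong, succinate = strong, myoinositol = strong,
      glycine = strong, creatine = strong, lactate = strong,
      formate = -strong, aspartate = -strong)
  # class 8: class 5 + a mild generic chemotherapy response
  off["8", ] <- off["5", ]
  add(8, lactate = weak, formate = -weak)
  # class 9: class 6 + chemotherapy response in cancer tissue
  off["9", ] <- off["6", ]
  add(9, lactate = strong, formate = -strong)
  effect_table(off)
}

# metabolite roster used by the default effect table (TSP excluded: the
# reference compound carries no biology)
default_signature_names <- function() {
  mets <- c("leucine", "isoleucine", "valine", "3-hydroxybutyrate", "lactate",
            "alanine", "acetate", "propionate", "glutamate", "glutamine",
            "succinate", "citrate", "aspartate", "creatine", "choline",
            "phosphocholine", "glycerophosphocholine", "taurine",
            "myoinositol", "glycine", "fumarate", "inosine", "hypoxanthine",
            "ADP", "formate")
  stats::setNames(seq_along(mets), mets)
}

#' @export
print.EffectTable <- function(x, ...) {
  nz <- colSums(x$offsets != 0) > 0
  cat(sprintf("EffectTable: %d classes x %d metabolites (%d with effects)\n",
              nrow(x$offsets), ncol(x$offsets), sum(nz)))
  invisible(x)
}
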