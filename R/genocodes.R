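# Cross algebra for the four segregation types of an outbred ("cp") cross.
# Dam haplotypes are labelled a/b, sire haplotypes c/d; by convention a and c
# carry the first allele of the parental genotype string (e.g. for ef x eg,
# a = e, b = f, c = e, d = g).

SEG_TYPES <- c("nnxnp", "lmxll", "efxeg", "hkxhk")

# legal observed (raw) genotype codes per segregation type
.seg_raw_codes <- list(
  nnxnp = c("nn", "np"),
  lmxll = c("ll", "lm"),
  efxeg = c("ee", "ef", "eg", "fg"),
  hkxhk = c("hh", "hk", "kk")
)

# Mendelian expectations over the raw code classes (order as above)
.seg_expected <- list(
  nnxnp = c(1, 1) / 2,
  lmxll = c(1, 1) / 2,
  efxeg = c(1, 1, 1, 1) / 4,
  hkxhk = c(1, 2, 1) / 4
)

# raw code -> dam haplotype label ("a"/"b", NA when uninformative or ambiguous)
.dam_of <- list(
  nnxnp = c(nn = NA, np = NA),
  lmxll = c(ll = "a", lm = "b"),
  efxeg = c(ee = "a", eg = "a", ef = "b", fg = "b"),
  hkxhk = c(hh = "a", hk = NA, kk = "b")
)

# raw code -> sire haplotype label ("c"/"d")
.sire_of <- list(
  nnxnp = c(nn = "c", np = "d"),
  lmxll = c(ll = NA, lm = NA),
  efxeg = c(ee = "c", eg = "d", ef = "c", fg = "d"),
  hkxhk = c(hh = "c", hk = NA, kk = "d")
)

# phase-code dialect used in geno.csv: first letter dam contribution, second
# sire contribution; one-sided codes for one-parent-informative types; the
# unresolvable hk x hk heterozygote is written "hk".
.raw_to_phase_map <- list(
  nnxnp = c(nn = "-c", np = "-d"),
  lmxll = c(ll = "a-", lm = "b-"),
  efxeg = c(ee = "ac", eg = "ad", ef = "bc", fg = "bd"),
  hkxhk = c(hh = "ac", kk = "bd", hk = "hk")
)

.phase_to_raw_map <- lapply(.raw_to_phase_map, function(m) {
  stats::setNames(names(m), unname(m))
})

#' Resolve an observed genotype to parental haplotype contributions
#'
#' Applies the cross algebra of a four-way cross: given a marker's segregation
#' type and an observed genotype code, returns which dam haplotype (a/b) and
#' which sire haplotype (c/d) the offspring inherited, where resolvable.
#' The `hk` heterozygote of an hkxhk marker is ambiguous for both parents.
#'
#' @param seg_type one of `"nnxnp"`, `"lmxll"`, `"efxeg"`, `"hkxhk"`.
#' @param raw character vector of observed codes (e.g. `"fg"`); `NA` = missing.
#' @return list with character vectors `dam` (values `"a"`/`"b"`/`NA`) and
#'   `sire` (values `"c"`/`"d"`/`NA`).
#' @examples
#' resolve_genotype("efxeg", c("fg", "ee", "hk"))
#' @export
resolve_genotype <- function(seg_type, raw) {
  seg_type <- match.arg(seg_type, SEG_TYPES)
  bad <- !is.na(raw) & !(raw %in% .seg_raw_codes[[seg_type]])
  if (any(bad)) {
    stop("illegal genotype code(s) for ", seg_type, ": ",
         paste(unique(raw[bad]), collapse = ", "))
  }
  list(dam = unname(.dam_of[[seg_type]][raw]),
       sire = unname(.sire_of[[seg_type]][raw]))
}

# observed raw code implied by the true haplotype pair
.raw_from_hap <- function(seg_type, dam, sire) {
  switch(seg_type,
    nnxnp = ifelse(sire == "c", "nn", "np"),
    lmxll = ifelse(dam == "a", "ll", "lm"),
    efxeg = ifelse(dam == "a", ifelse(sire == "c", "ee", "eg"),
                   ifelse(sire == "c", "ef", "fg")),
    hkxhk = ifelse(dam == "a", ifelse(sire == "c", "hh", "hk"),
                   ifelse(sire == "c", "hk", "kk")),
    stop("unknown segregation type: ", seg_type))
}

.raw_to_phase <- function(seg_type, raw) {
  out <- unname(.raw_to_phase_map[[seg_type]][raw])
  out[is.na(raw)] <- NA_character_
  out
}

.phase_to_raw <- function(seg_type, code) {
  out <- unname(.phase_to_raw_map[[seg_type]][code])
  out[is.na(code)] <- NA_character_
  out
}

# accept either raw allele-pair codes or phase codes; normalise to raw
.normalise_code <- function(seg_type, code) {
  code[code %in% c("-", "")] <- NA_character_
  is_phase <- !is.na(code) & code %in% names(.phase_to_raw_map[[seg_type]])
  # "hk" is both a raw code and a phase code for hkxhk; identical meaning
  out <- code
  out[is_phase] <- .phase_to_raw(seg_type, code[is_phase])
  out
}
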