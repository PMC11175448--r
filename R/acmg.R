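#' ACMG/AMP evidence-code combination
#'
#' Implements the five-tier evidence-combination rules of the ACMG/AMP
#' sequence-variant interpretation guideline: evidence codes (PVS1, PS1-PS4,
#' PM1-PM6, PP1-PP5 on the pathogenic side; BA1, BS1-BS4, BP1-BP7 on the
#' benign side) are counted at their strength level and combined into
#' Pathogenic, Likely pathogenic, Uncertain significance, Likely benign or
#' Benign. Evidence codes are an input to this engine (curation of which
#' criteria fire for a variant is a separate concern); only the combination
#' logic lives here.
#'
#' @name acmg
NULL

ACMG_CODES <- c("PVS1",
                paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
                "BA1", paste0("BS", 1:4), paste0("BP", 1:7))

ACMG_DEFAULT_STRENGTH <- c(
  PVS1 = "very_strong",
  setNames(rep("strong", 4), paste0("PS", 1:4)),
  setNames(rep("moderate", 6), paste0("PM", 1:6)),
  setNames(rep("supporting", 5), paste0("PP", 1:5)),
  BA1 = "stand_alone",
  setNames(rep("strong", 4), paste0("BS", 1:4)),
  setNames(rep("supporting", 7), paste0("BP", 1:7)))

#' Parse evidence codes with optional strength modifiers
#'
#' Codes are given as `"PM2"` or with an explicit strength, `"PVS1_moderate"`
#' / `"PS1_supporting"`; valid strengths are `very_strong`, `strong`,
#' `moderate`, `supporting` and (for BA1 only) `stand_alone`. Duplicate base
#' codes are rejected.
#'
#' @param codes character vector of codes.
#' @return a data.frame with columns `code`, `strength`, `side`.
#' @export
parse_evidence <- function(codes) {
  if (!length(codes))
    return(data.frame(code = character(), strength = character(),
                      side = character(), stringsAsFactors = FALSE))
  base <- sub("_.*$", "", codes)
  strength <- ifelse(grepl("_", codes), sub("^[^_]*_", "", codes),
                     ACMG_DEFAULT_STRENGTH[base])
  bad <- which(!base %in% ACMG_CODES)
  if (length(bad)) stop("unknown ACMG evidence code: ", codes[bad[1]])
  valid_s <- c("very_strong", "strong", "moderate", "supporting", "stand_alone")
  bad <- which(!strength %in% valid_s)
  if (length(bad)) stop("invalid strength modifier in: ", codes[bad[1]])
  if (anyDuplicated(base))
    stop("duplicate evidence code: ", base[duplicated(base)][1])
  side <- ifelse(substr(base, 1, 1) == "P", "pathogenic", "benign")
  if (any(side == "benign" & strength == "very_strong") ||
      any(strength == "stand_alone" & base != "BA1"))
    stop("stand_alone is reserved for BA1; benign codes cannot be very_strong")
  data.frame(code = base, strength = strength, side = side,
             stringsAsFactors = FALSE)
}

#' Combine ACMG/AMP evidence codes into a five-tier classification
#'
#' Pathogenic combinations: (i) 1 very-strong with >=1 strong, >=2 moderate,
#' 1 moderate + 1 supporting, or >=2 supporting; (ii) >=2 strong; (iii) 1
#' strong with >=3 moderate, 2 moderate + >=2 supporting, or 1 moderate +
#' >=4 supporting. Likely pathogenic: 1 very-strong + 1 moderate; 1 strong +
#' 1-2 moderate; 1 strong + >=2 supporting; >=3 moderate; 2 moderate + >=2
#' supporting; 1 moderate + >=4 supporting. Benign: BA1, or >=2 benign
#' strong. Likely benign: 1 benign strong + 1 benign supporting, or >=2
#' benign supporting. A match on both the pathogenic and the benign side
#' forces Uncertain significance, as does no match at all.
#'
#' With `modified_strengths = TRUE` (default) a strength-modified code
#' counts in its modified slot (e.g. `PS1_moderate` counts as a moderate).
#' With `FALSE`, modifiers are ignored and every code counts at its default
#' strength.
#'
#' @param codes character vector of evidence codes (see [parse_evidence()]).
#' @param modified_strengths honour strength modifiers (default TRUE).
#' @return list with `tier` (one of `"Pathogenic"`, `"Likely pathogenic"`,
#'   `"Uncertain significance"`, `"Likely benign"`, `"Benign"`),
#'   `fired_rules` (character vector) and `conflict` (logical).
#' @export
acmg_combine <- function(codes, modified_strengths = TRUE) {
  ev <- parse_evidence(codes)
  if (!modified_strengths) ev$strength <- ACMG_DEFAULT_STRENGTH[ev$code]
  p <- ev[ev$side == "pathogenic", ]
  b <- ev[ev$side == "benign", ]
  nvs <- sum(p$strength == "very_strong")
  ns  <- sum(p$strength == "strong")
  nm  <- sum(p$strength == "moderate")
  np  <- sum(p$strength == "supporting")
  ba  <- sum(b$strength == "stand_alone")
  nbs <- sum(b$strength == "strong")
  nbp <- sum(b$strength == "supporting")

  fired <- character()
  if (nvs >= 1 && ns >= 1) fired <- c(fired, "P_ia")
  if (nvs >= 1 && nm >= 2) fired <- c(fired, "P_ib")
  if (nvs >= 1 && nm >= 1 && np >= 1) fired <- c(fired, "P_ic")
  if (nvs >= 1 && np >= 2) fired <- c(fired, "P_id")
  if (ns >= 2) fired <- c(fired, "P_ii")
  if (ns >= 1 && nm >= 3) fired <- c(fired, "P_iiia")
  if (ns >= 1 && nm >= 2 && np >= 2) fired <- c(fired, "P_iiib")
  if (ns >= 1 && nm >= 1 && np >= 4) fired <- c(fired, "P_iiic")
  if (nvs >= 1 && nm >= 1) fired <- c(fired, "LP_i")
  if (ns >= 1 && nm >= 1) fired <- c(fired, "LP_ii")
  if (ns >= 1 && np >= 2) fired <- c(fired, "LP_iii")
  if (nm >= 3) fired <- c(fired, "LP_iv")
  if (nm >= 2 && np >= 2) fired <- c(fired, "LP_v")
  if (nm >= 1 && np >= 4) fired <- c(fired, "LP_vi")
  if (ba >= 1) fired <- c(fired, "B_i")
  if (nbs >= 2) fired <- c(fired, "B_ii")
  if (nbs >= 1 && nbp >= 1) fired <- c(fired, "LB_i")
  if (nbp >= 2) fired <- c(fired, "LB_ii")

  patho_tier <- if (any(startsWith(fired, "P_"))) "Pathogenic"
    else if (any(startsWith(fired, "LP_"))) "Likely pathogenic" else NA
  benign_tier <- if (any(fired %in% c("B_i", "B_ii"))) "Benign"
    else if (any(startsWith(fired, "LB_"))) "Likely benign" else NA
  conflict <- !is.na(patho_tier) && !is.na(benign_tier)
  tier <- if (conflict || (is.na(patho_tier) && is.na(benign_tier)))
    "Uncertain significance"
  else if (!is.na(patho_tier)) patho_tier else benign_tier
  list(tier = tier, fired_rules = fired, conflict = conflict)
}
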