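# Pigment-content statistics: chlorophyll a+b, lutein, and total carotene
# expressed as percent of biomass dry weight, compared across light
# intensities, growth phases, carbon sources, and weak-light treatments
# by Welch t-tests on replicate groups (n is typically 3).

PIGMENTS <- c("chl_ab", "lutein", "carotene")

#' Pigment mass as percent of dry weight
#'
#' @param pigment_mass_ug Pigment mass in micrograms.
#' @param dry_weight_mg Biomass dry weight in milligrams, positive.
#' @return Pigment content in percent of dry weight.
#' @examples
#' percent_dw(50, 1)  # 5 %DW, a chlorophyll-rich culture
#' percent_dw(6, 1)   # 0.6 %DW, a high lutein content
#' @export
percent_dw <- function(pigment_mass_ug, dry_weight_mg) {
  if (any(dry_weight_mg <= 0))
    stop("dry weight must be positive", call. = FALSE)
  100 * (pigment_mass_ug / 1000) / dry_weight_mg
}

#' Assemble a pigment record table
#'
#' One row per replicate measurement. `mode` is `"photoautotrophic"` or
#' `"heterotrophic"`; `light` is the incident intensity in umol m^-2 s^-1
#' (for heterotrophic rows, 0 for darkness or the weak-light intensity);
#' `phase` is `"exponential"`, `"deceleration"`, or
#' `"heterotrophic-sample"`.
#'
#' @param species,mode,light,substrate,phase,pigment,replicate,percent_dw
#'   Vectors (recycled to a common length) describing each measurement.
#' @return A data frame of class `pigment_records`.
#' @export
pigment_records <- function(species, mode, light, substrate, phase, pigment,
                            replicate, percent_dw) {
  df <- data.frame(species = species, mode = mode, light = light,
                   substrate = substrate, phase = phase, pigment = pigment,
                   replicate = replicate, percent_dw = percent_dw,
                   stringsAsFactors = FALSE)
  if (any(df$percent_dw < 0))
    stop("pigment content must be non-negative", call. = FALSE)
  if (any(df$percent_dw >= 100))
    stop("pigment content must be below 100 %DW", call. = FALSE)
  class(df) <- c("pigment_records", "data.frame")
  df
}

#' Read a pigment table from delimited text
#'
#' Header columns: `species, mode, light, substrate, phase, pigment,
#' replicate, percent_dw`.
#'
#' @param path Path to the file.
#' @param sep Field separator (default comma).
#' @return A [pigment_records()] data frame.
#' @export
read_pigment_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("species", "mode", "light", "substrate", "phase", "pigment",
            "replicate", "percent_dw")
  if (!all(need %in% names(df)))
    stop(sprintf("pigment file '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  do.call(pigment_records, df[need])
}

#' Heterotrophic pigment content relative to the photoautotrophic reference
#'
#' Expresses the mean pigment content of a heterotrophic condition as a
#' percentage of the average content during the deceleration phase of
#' light-limited photoautotrophy, the reference being the mean over the
#' light intensities present (per-intensity replicate means averaged with
#' equal weight).
#'
#' @param het [pigment_records()] rows for one heterotrophic condition
#'   (one species, one pigment).
#' @param photo_dec [pigment_records()] rows for the photoautotrophic
#'   deceleration phase of the same species and pigment, covering at least
#'   2 intensities.
#' @return List with `percentage`, `het_mean`, `reference_mean`, and
#'   `intensities` used for the reference.
#' @export
reference_percentage <- function(het, photo_dec) {
  het <- as.data.frame(het); photo_dec <- as.data.frame(photo_dec)
  if (length(unique(het$species)) != 1L || length(unique(het$pigment)) != 1L)
    stop("heterotrophic records must cover one species and one pigment",
         call. = FALSE)
  if (!identical(unique(het$species), unique(photo_dec$species)) ||
      !identical(unique(het$pigment), unique(photo_dec$pigment)))
    stop("species/pigment mismatch between heterotrophic and reference records",
         call. = FALSE)
  ints <- sort(unique(photo_dec$light))
  if (length(ints) < 2L)
    stop("reference needs at least 2 light intensities", call. = FALSE)
  per_int <- vapply(ints, function(I)
    mean(photo_dec$percent_dw[photo_dec$light == I]), numeric(1))
  ref <- mean(per_int)
  hm <- mean(het$percent_dw)
  list(percentage = 100 * hm / ref, het_mean = hm, reference_mean = ref,
       intensities = ints)
}

#' Welch t-test contrast between two replicate groups
#'
#' Two-sided Welch (unequal-variance) t-test; `significant` flags
#' `p < alpha`. Two identical zero-variance groups are reported with p = 1
#' and flagged as degenerate (zero-variance groups with different means
#' are flagged with p = 0).
#'
#' @param group_a,group_b Numeric vectors of replicate values, each of
#'   length at least 2.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `contrast_result`: list with `estimate`
#'   (mean of `group_a` minus mean of `group_b`), `p_value`,
#'   `significant`, `alpha`, and `degenerate`.
#' @export
contrast <- function(group_a, group_b, alpha = 0.05) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  est <- mean(group_a) - mean(group_b)
  degenerate <- stats::sd(group_a) == 0 && stats::sd(group_b) == 0
  if (degenerate) {
    p <- if (est == 0) 1 else 0
  } else {
    p <- stats::t.test(group_a, group_b, var.equal = FALSE)$p.value
  }
  structure(list(estimate = est, p_value = p,
                 significant = p < alpha, alpha = alpha,
                 degenerate = degenerate),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("Contrast: difference = %.4g, p = %.4g (%ssignificant at %.2g)%s\n",
              x$estimate, x$p_value, if (x$significant) "" else "not ",
              x$alpha, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Run the standard pigment contrast design
#'
#' Builds one Welch contrast per design cell:
#' * `light` — each photoautotrophic intensity against the 300
#'   umol m^-2 s^-1 reference, per phase and pigment;
#' * `phase` — deceleration against exponential, per intensity and pigment;
#' * `weaklight` — weak light against darkness, per substrate and pigment
#'   (heterotrophic rows);
#' * `substrate` — acetate against glucose in darkness, per pigment.
#'
#' Cells missing from the data are listed in the `missing_cells` attribute
#' rather than raising an error.
#'
#' @param records A [pigment_records()] data frame.
#' @param design Character vector choosing which contrast families to run.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Optional p-value adjustment method (e.g. `"BH"`);
#'   `"none"` (the default) matches a per-comparison alpha.
#' @return Data frame with one row per contrast: `design`, `species`,
#'   `pigment`, `cell`, `reference`, `estimate`, `p_value`, `significant`.
#' @export
effect_table <- function(records,
                         design = c("light", "phase", "weaklight", "substrate"),
                         alpha = 0.05, p_adjust = "none") {
  design <- match.arg(design, several.ok = TRUE)
  empty <- data.frame(design = character(), species = character(),
                      pigment = character(), cell = character(),
                      reference = character(), estimate = numeric(),
                      p_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0L) {
    attr(empty, "missing_cells") <- character()
    return(empty)
  }
  df <- as.data.frame(records)
  rows <- list(); missing <- character()
  add <- function(fam, sp, pg, cell_lab, ref_lab, g_cell, g_ref) {
    if (length(g_cell) < 2L || length(g_ref) < 2L) {
      missing[[length(missing) + 1L]] <<-
        sprintf("%s:%s:%s:%s vs %s", fam, sp, pg, cell_lab, ref_lab)
      return(invisible())
    }
    ct <- contrast(g_cell, g_ref, alpha)
    rows[[length(rows) + 1L]] <<- data.frame(
      design = fam, species = sp, pigment = pg, cell = cell_lab,
      reference = ref_lab, estimate = ct$estimate, p_value = ct$p_value,
      significant = ct$significant, stringsAsFactors = FALSE)
  }
  photo <- df[df$mode == "photoautotrophic", ]
  het <- df[df$mode == "heterotrophic", ]
  for (sp in unique(df$species)) {
    for (pg in unique(df$pigment)) {
      if ("light" %in% design && nrow(photo)) {
        for (ph in intersect(unique(photo$phase),
                             c("exponential", "deceleration"))) {
          sub <- photo[photo$species == sp & photo$pigment == pg &
                         photo$phase == ph, ]
          if (!nrow(sub)) next
          ref <- sub$percent_dw[sub$light == 300]
          for (I in setdiff(sort(unique(sub$light)), 300)) {
            add("light", sp, pg, sprintf("%g umol (%s)", I, ph),
                sprintf("300 umol (%s)", ph),
                sub$percent_dw[sub$light == I], ref)
          }
        }
      }
      if ("phase" %in% design && nrow(photo)) {
        sub <- photo[photo$species == sp & photo$pigment == pg, ]
        for (I in sort(unique(sub$light))) {
          add("phase", sp, pg, sprintf("deceleration (%g umol)", I),
              sprintf("exponential (%g umol)", I),
              sub$percent_dw[sub$light == I & sub$phase == "deceleration"],
              sub$percent_dw[sub$light == I & sub$phase == "exponential"])
        }
      }
      if ("weaklight" %in% design && nrow(het)) {
        sub <- het[het$species == sp & het$pigment == pg, ]
        for (s in unique(sub$substrate)) {
          add("weaklight", sp, pg, sprintf("%s + weak light", s),
              sprintf("%s, dark", s),
              sub$percent_dw[sub$substrate == s & sub$light > 0],
              sub$percent_dw[sub$substrate == s & sub$light == 0])
        }
      }
      if ("substrate" %in% design && nrow(het)) {
        sub <- het[het$species == sp & het$pigment == pg & het$light == 0, ]
        add("substrate", sp, pg, "acetate, dark", "glucose, dark",
            sub$percent_dw[sub$substrate == "acetate"],
            sub$percent_dw[sub$substrate == "glucose"])
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out) && p_adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
    out$significant <- out$p_value < alpha
  }
  attr(out, "missing_cells") <- unlist(missing)
  out
}
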