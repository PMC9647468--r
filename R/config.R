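#' Default scoring configuration
#'
#' All scoring constants live in configuration rather than code: the disease
#' catalogue (code -> severity 0-3, seeded with the NRS-2002 prototype
#' categories), the PG-SGA-SF point maps, and the at-risk cutoffs (NRS-2002
#' total >= 3, PG-SGA-SF total >= 4). The PG-SGA-SF maps are a documented
#' default consistent with the published worksheet's ordering; deployments
#' that know their tool's exact mapping should override them via YAML.
#'
#' @return A list with components `version`, `cutoffs`, `disease_catalogue`,
#'   and `pgsgasf` (point maps `weight_change`, `one_month_bonus`,
#'   `intake_reduction`, `diet_texture`, `appetite`).
#' @seealso [read_scoring_config()], [scoring_config_hash()]
#' @export
default_scoring_config <- function() {
  list(
    version = "default-1.0",
    cutoffs = list(nrs2002 = 3L, pgsgasf = 4L),
    disease_catalogue = c(
      # NRS-2002 prototype severity grades
      hip_fracture            = 1L,
      chronic_disease         = 1L,
      copd                    = 1L,
      diabetes                = 1L,
      solid_tumor             = 1L,
      hemodialysis            = 1L,
      cirrhosis               = 1L,
      major_abdominal_surgery = 2L,
      stroke                  = 2L,
      severe_pneumonia        = 2L,
      hematologic_malignancy  = 2L,
      head_injury             = 3L,
      bone_marrow_transplant  = 3L,
      intensive_care          = 3L,
      none                    = 0L
    ),
    pgsgasf = list(
      weight_change = c(stable_or_gain = 0L, loss_5_to_15pct = 3L,
                        loss_over_15pct = 4L),
      one_month_bonus = 1L,  # added when the loss occurred within 1 month
      intake_reduction = c(unchanged = 0L, reduction_25_50 = 1L,
                           reduction_50_75 = 2L, reduction_75_100 = 3L),
      diet_texture = c(normal = 0L, soft = 1L, liquid = 2L, fasting = 4L),
      appetite = c(never = 0L, occasionally = 1L, frequently = 3L)
    )
  )
}

#' Default food composition table
#'
#' Energy and protein densities (per 100 g, or 100 mL for milk) for the three
#' reported food groups, plus calibration terms: per-item multiplicative
#' adjustments that stand in for the unreported foods (cooking oil,
#' vegetables, ...) a pilot dietary survey would fold into such an algorithm,
#' and additive daily intercepts. These defaults are plausible values for
#' cooked rice, cooked mixed meat and whole milk; they are a shipped
#' configuration, not a published calibration, and are meant to be replaced
#' by survey-derived coefficients where those exist.
#'
#' @return A `food_composition_table`: list with `version`, `items` (each of
#'   `rice`, `meat`, `milk` holding `energy_density`, `protein_density`,
#'   `adjustment`), and `intercepts` (`energy`, `protein`).
#' @export
default_food_table <- function() {
  tbl <- list(
    version = "default-1.0",
    items = list(
      rice = list(energy_density = 116, protein_density = 2.6, adjustment = 1.25),
      meat = list(energy_density = 250, protein_density = 20.0, adjustment = 1.25),
      milk = list(energy_density = 65,  protein_density = 3.0,  adjustment = 1.25)
    ),
    intercepts = list(energy = 0, protein = 0)
  )
  validate_food_table(tbl)
}

#' @rdname default_food_table
#' @param table A candidate food-composition table (list as above).
#' @export
validate_food_table <- function(table) {
  stopifnot(is.list(table), is.character(table$version),
            nzchar(table$version))
  need <- c("rice", "meat", "milk")
  miss <- setdiff(need, names(table$items))
  if (length(miss)) {
    stop("food table missing item(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (nm in need) {
    it <- table$items[[nm]]
    if (!is.finite(it$energy_density) || it$energy_density < 0 ||
        !is.finite(it$protein_density) || it$protein_density < 0) {
      stop("densities for '", nm, "' must be finite and >= 0", call. = FALSE)
    }
    if (is.null(it$adjustment)) it$adjustment <- 1
    if (!is.finite(it$adjustment) || it$adjustment <= 0) {
      stop("adjustment for '", nm, "' must be > 0", call. = FALSE)
    }
    table$items[[nm]] <- it
  }
  if (is.null(table$intercepts)) table$intercepts <- list(energy = 0, protein = 0)
  if (table$intercepts$energy < 0 || table$intercepts$protein < 0) {
    stop("intercepts must be >= 0", call. = FALSE)
  }
  class(table) <- "food_composition_table"
  table
}

#' Read / write configuration as YAML
#'
#' Scoring configuration and food-composition tables round-trip through YAML
#' so that deployments can version them outside the package. Integer-valued
#' maps are restored as integers.
#'
#' @param path File path.
#' @return `read_scoring_config()` returns a scoring-config list;
#'   `read_food_table()` a validated `food_composition_table`.
#' @export
read_scoring_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$cutoffs), !is.null(cfg$disease_catalogue),
            !is.null(cfg$pgsgasf))
  cfg$cutoffs <- lapply(cfg$cutoffs, as.integer)
  cfg$disease_catalogue <- vapply(cfg$disease_catalogue, as.integer, integer(1))
  cfg$pgsgasf <- lapply(cfg$pgsgasf, function(x) {
    if (is.list(x)) vapply(x, as.integer, integer(1)) else as.integer(x)
  })
  cfg
}

# YAML writes named atomic vectors as plain sequences, losing the names;
# serialise them as maps instead.
yamlable <- function(x) {
  if (is.list(x)) {
    lapply(x, yamlable)
  } else if (!is.null(names(x)) && length(x) > 1) {
    as.list(x)
  } else {
    x
  }
}

#' @rdname read_scoring_config
#' @param config A scoring-config list or food table.
#' @export
write_scoring_config <- function(config, path) {
  yaml::write_yaml(yamlable(unclass(config)), path)
  invisible(path)
}

#' @rdname read_scoring_config
#' @export
read_food_table <- function(path) {
  validate_food_table(yaml::read_yaml(path))
}

#' @rdname read_scoring_config
#' @export
write_food_table <- function(table, path) {
  yaml::write_yaml(yamlable(unclass(table)), path)
  invisible(path)
}

#' Content hash of a configuration
#'
#' MD5 hash of the canonical YAML serialisation, logged with every scoring
#' run so results can be traced to the exact configuration that produced them.
#'
#' @param config Scoring config or food table (any YAML-serialisable list).
#' @return Lower-case 32-character MD5 string.
#' @export
scoring_config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  yaml::write_yaml(yamlable(unclass(config)), tf)
  unname(tools::md5sum(tf))
}
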