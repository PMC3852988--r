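# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# single-month signal scenario: strong truth, shore-biased effort
signal_scenario <- function() fixture("signal", function()
  make_scenario(list(months = "August", monthly_n = c(August = 300L)),
                seed = 7))

# uniform-truth, uniform-effort null scenario
null_scenario <- function() fixture("null", function()
  make_scenario(list(months = "August", monthly_n = c(August = 200L),
                     coefficients = numeric(0), effort_bias = FALSE),
                seed = 11))

# sparse truth (two active variables) for AICc selection checks
sparse_scenario <- function() fixture("sparse", function()
  make_scenario(list(months = "August", monthly_n = c(August = 150L),
                     coefficients = c(dist_150 = -5, chl_a = 2),
                     effort_bias = FALSE), seed = 3))

scenario_presences <- function(sc, month = names(sc$stacks)[1]) {
  fixture(paste0("pres_", month, "_", sc$seed), function()
    presences_to_cells(sc$sightings, sc$stacks[[month]]$layers$depth, month))
}

# hand-built feature expansion for white-box maxent tests
manual_fe <- function(design, presence_rows,
                      meta = data.frame(
                        class = rep("linear", ncol(design)),
                        var1 = paste0("v", seq_len(ncol(design))),
                        var2 = NA_character_, knot = NA_real_,
                        id = sprintf("f%03d", seq_len(ncol(design))))) {
  vars <- unique(c(meta$var1, meta$var2[!is.na(meta$var2)]))
  structure(
    list(design = design, feature_meta = meta,
         presence_rows = presence_rows,
         background_rows = seq_len(nrow(design)),
         cells = seq_len(nrow(design)), env = design,
         variables = vars, classes = unique(meta$class),
         knots_per_variable = 0L,
         scaling = list(vmin = rep(0, ncol(design)),
                        vmax = rep(1, ncol(design)), knots = list())),
    class = "feature_expansion")
}

# small grid helper
mk_grid <- function(values, cell_size = 2500, x0 = 0, y0 = 0)
  grid_layer(values, x0, y0, cell_size)
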