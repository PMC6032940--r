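# Regenerates the plain-text fixtures shipped under inst/extdata/.
# Run from the package root with the package installed:
#   Rscript data-raw/make_fixtures.R
library(debipm)

white <- make_white_series(seed = 1)
blue <- recolour_series(white, "blue", seed = 2)
red <- recolour_series(white, "red", seed = 3)
write_food_series(white, "inst/extdata/food_series_white.tsv")
write_food_series(blue, "inst/extdata/food_series_blue.tsv")
write_food_series(red, "inst/extdata/food_series_red.tsv")

# one synthetic study at package defaults (the filename marks it synthetic:
# it is generated output, not laboratory data)
tab <- generate_study(seed = 1)
write_census_table(tab, "inst/extdata/synthetic_census_default.csv")
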