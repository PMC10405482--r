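#!/usr/bin/env Rscript
# Stage 3: the statistical layer.
#
# Group association table (standardized beta of group for each MRI measure,
# univariable and age/sex-adjusted) and the VEGFA association table within
# patients after upper-tail IQR outlier removal on plasma VEGFA.

library(bbbpatlak)

fitted <- utils::read.csv("results/cohort_fitted.csv", stringsAsFactors = FALSE)
reports <- write_reports(fitted, "results/reports")

cat("\nGroup associations (control=0 / patient=1):\n")
print(reports$table1$associations, row.names = FALSE, digits = 3)
cat("\nVEGFA associations in patients (", reports$table2$n_outliers,
    "outlier(s) removed ):\n")
print(reports$table2$associations, row.names = FALSE, digits = 3)
cat("\nReports written to results/reports/\n")
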