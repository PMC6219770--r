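# Write a data.frame to XLSX through the system python + openpyxl, used to
# fabricate spreadsheet fixtures at test time (no XLSX writer exists on the
# R side, and binary fixtures are not stored in the repository).
write_xlsx_via_python <- function(df, path, colnames = names(df)) {
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv))
  utils::write.csv(stats::setNames(df, colnames), csv, row.names = FALSE,
                   na = "")
  script <- sprintf("
import csv, openpyxl
wb = openpyxl.Workbook(); ws = wb.active
with open(%s) as fh:
    for row in csv.reader(fh):
        out = []
        for cell in row:
            try:
                out.append(float(cell) if cell != '' else None)
            except ValueError:
                out.append(cell)
        ws.append(out)
wb.save(%s)
", shQuote(csv), shQuote(path))
  status <- system2("python", c("-c", shQuote(script)))
  if (status != 0) stop("python/openpyxl XLSX writer failed")
  invisible(path)
}
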