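# printed percents of the published allele-count table (NA where the table
# prints a bare count); order matches the bundled fixture rows
printedPercents <- function() {
    txt <- "
pos      sample tissue refPct altPct
21341446 P1     .      45     55
21341446 P1     Ad     NA     NA
21341446 P1     Ln     5      95
21341446 P1     Hr     NA     NA
21341446 P1     Ov     NA     NA
21341446 P2     .      38     63
21341446 P2     Ad     NA     NA
21341446 P2     Ln     NA     NA
21341446 P2     Hr     NA     NA
21341446 P2     Ov     NA     NA
21349510 P1     .      47     53
21349510 P1     Ad     NA     NA
21349510 P1     Ln     NA     NA
21349510 P1     Hr     NA     NA
21349510 P1     Ov     NA     NA
21349510 P2     .      42     58
21349510 P2     Ad     NA     NA
21349510 P2     Ln     NA     NA
21349510 P2     Hr     NA     NA
21349510 P2     Ov     NA     NA
21349510 P3     .      32     68
21349510 P3     Ad     100    NA
21349510 P3     Ln     100    NA
21349510 P3     Hr     NA     NA
21349510 P3     Ov     NA     NA
21365021 P2     .      60     40
21365021 P2     Ad     98     2
21365021 P2     Ln     100    NA
21365021 P2     Hr     NA     NA
21365021 P2     Ov     NA     NA
21368747 P3     .      38     62
21368747 P3     Ad     97     3
21368747 P3     Ln     98     2
21368747 P3     Hr     NA     NA
21368747 P3     Ov     97     3
"
    read.table(text = txt, header = TRUE, na.strings = "NA")
}

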