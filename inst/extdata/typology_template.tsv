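# Template: typological genus counts per noun-phrase order.
# Fill genus_count from a typological survey; orders use slots
# D (determiner), N (numeral), A (adjective), n (noun).
# An order and its reversal share one predictive-information value.
order	genus_count
D-N-A-n	NA
D-N-n-A	NA
D-A-N-n	NA
D-A-n-N	NA
D-n-N-A	NA
D-n-A-N	NA
N-D-A-n	NA
N-D-n-A	NA
N-A-D-n	NA
N-A-n-D	NA
N-n-D-A	NA
N-n-A-D	NA
A-D-N-n	NA
A-D-n-N	NA
A-N-D-n	NA
A-N-n-D	NA
A-n-D-N	NA
A-n-N-D	NA
n-D-N-A	NA
n-D-A-N	NA
n-N-D-A	NA
n-N-A-D	NA
n-A-D-N	NA
n-A-N-D	NA
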