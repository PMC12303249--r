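# Default keyword lexicon: phrases that may indicate access to germline
# genetic testing in breast-cancer care. One phrase per line, matched
# case-insensitively as whole words. Substitute your own list via
# read_lexicon().
genetic testing
germline
genetic counseling
BRCA
BRCA1
BRCA2
PALB2
CHEK2
ATM
TP53
CDH1
STK11
PTEN
pathogenic variant
hereditary breast
genomic medicine service
clinical cancer genetics
gene panel
Myriad
Invitae
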