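## Shared constants (loaded first).

## The seven binding classes, canonical order. X = non-site.
CLASSES7 <- c("X", "P", "R", "A", "G", "C", "U")
CLASSES4_COARSE <- c("X", "P", "R", "B")
BASES <- c("A", "G", "C", "U")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
RNA_RESNAMES <- c("A", "G", "C", "U")
DNA_RESNAMES <- c("DA", "DG", "DC", "DT")

## Moiety boundaries at the phosphodiester / glycosidic bonds. Legacy PDB
## naming (O1P/O2P, primes as '*') is normalized before lookup.
PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "OP3", "O5'")
RIBOSE_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O2'", "O3'")
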