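metabolite,formula,pathway,representative
alanine,C3H7NO2,amino_acids,FALSE
arginine,C6H14N4O2,amino_acids,FALSE
asparagine,C4H8N2O3,amino_acids,FALSE
aspartate,C4H7NO4,amino_acids,FALSE
cysteine,C3H7NO2S,amino_acids,FALSE
glutamine,C5H10N2O3,amino_acids,FALSE
glutamate,C5H9NO4,amino_acids,TRUE
glycine,C2H5NO2,amino_acids,FALSE
histidine,C6H9N3O2,amino_acids,FALSE
isoleucine,C6H13NO2,amino_acids,FALSE
leucine,C6H13NO2,amino_acids,FALSE
lysine,C6H14N2O2,amino_acids,FALSE
methionine,C5H11NO2S,amino_acids,FALSE
phenylalanine,C9H11NO2,amino_acids,FALSE
proline,C5H9NO2,amino_acids,FALSE
serine,C3H7NO3,amino_acids,FALSE
threonine,C4H9NO3,amino_acids,FALSE
tryptophan,C11H12N2O2,amino_acids,FALSE
tyrosine,C9H11NO3,amino_acids,FALSE
valine,C5H11NO2,amino_acids,FALSE
taurine,C2H7NO3S,amino_acid_derived,FALSE
hypotaurine,C2H7NO2S,amino_acid_derived,FALSE
creatine,C4H9N3O2,amino_acid_derived,TRUE
creatinine,C4H7N3O,amino_acid_derived,FALSE
phosphocreatine,C4H10N3O5P,amino_acid_derived,FALSE
guanidinoacetate,C3H7N3O2,amino_acid_derived,FALSE
sarcosine,C3H7NO2,amino_acid_derived,FALSE
betaine,C5H11NO2,amino_acid_derived,FALSE
choline,C5H13NO,amino_acid_derived,FALSE
carnitine,C7H15NO3,amino_acid_derived,FALSE
acetylcarnitine,C9H17NO4,amino_acid_derived,FALSE
N-acetylaspartate,C6H9NO5,amino_acid_derived,FALSE
N-acetylglutamate,C7H11NO5,amino_acid_derived,FALSE
homoserine,C4H9NO3,amino_acid_derived,FALSE
homocysteine,C4H9NO2S,amino_acid_derived,FALSE
cystathionine,C7H14N2O4S,amino_acid_derived,FALSE
cystine,C6H12N2O4S2,amino_acid_derived,FALSE
methionine-sulfoxide,C5H11NO3S,amino_acid_derived,FALSE
kynurenine,C10H12N2O3,amino_acid_derived,FALSE
anthranilate,C7H7NO2,amino_acid_derived,FALSE
serotonin,C10H12N2O,amino_acid_derived,FALSE
histamine,C5H9N3,amino_acid_derived,FALSE
GABA,C4H9NO2,amino_acid_derived,FALSE
beta-alanine,C3H7NO2,amino_acid_derived,FALSE
2-aminoadipate,C6H11NO4,amino_acid_derived,FALSE
2-aminobutyrate,C4H9NO2,amino_acid_derived,FALSE
O-phosphoethanolamine,C2H8NO4P,amino_acid_derived,FALSE
ethanolamine,C2H7NO,amino_acid_derived,FALSE
O-phosphoserine,C3H8NO6P,amino_acid_derived,FALSE
ornithine,C5H12N2O2,urea_cycle,FALSE
citrulline,C6H13N3O3,urea_cycle,TRUE
argininosuccinate,C10H18N4O6,urea_cycle,FALSE
urea,CH4N2O,urea_cycle,FALSE
hypoxanthine,C4H4N4O,purines,FALSE
xanthine,C5H4N4O2,purines,FALSE
urate,C5H4N4O3,purines,FALSE
adenine,C5H5N5,purines,FALSE
guanine,C5H5N5O,purines,FALSE
adenosine,C10H13N5O4,purines,FALSE
inosine,C10H12N4O5,purines,FALSE
guanosine,C10H13N5O5,purines,FALSE
AMP,C10H14N5O7P,purines,TRUE
ADP,C10H15N5O10P2,purines,FALSE
ATP,C10H16N5O13P3,purines,FALSE
GMP,C10H14N5O8P,purines,FALSE
GDP,C10H15N5O11P2,purines,FALSE
GTP,C10H16N5O14P3,purines,FALSE
IMP,C10H13N4O8P,purines,TRUE
adenylosuccinate,C14H18N5O11P,purines,FALSE
S-adenosylmethionine,C15H22N6O5S,purines,FALSE
S-adenosylhomocysteine,C14H20N6O5S,purines,FALSE
allantoin,C4H6N4O3,purines,FALSE
uracil,C4H4N2O2,pyrimidines,FALSE
uridine,C9H12N2O6,pyrimidines,FALSE
cytidine,C9H13N3O5,pyrimidines,FALSE
cytosine,C4H5N3O,pyrimidines,FALSE
thymine,C5H6N2O2,pyrimidines,FALSE
thymidine,C10H14N2O5,pyrimidines,FALSE
UMP,C9H13N2O9P,pyrimidines,TRUE
UDP,C9H14N2O12P2,pyrimidines,TRUE
UTP,C9H15N2O15P3,pyrimidines,TRUE
CMP,C9H14N3O8P,pyrimidines,FALSE
CDP,C9H15N3O11P2,pyrimidines,FALSE
CTP,C9H16N3O14P3,pyrimidines,FALSE
dTMP,C10H15N2O8P,pyrimidines,FALSE
dCMP,C9H14N3O7P,pyrimidines,FALSE
dUMP,C9H13N2O8P,pyrimidines,FALSE
carbamoyl-aspartate,C5H8N2O5,pyrimidines,FALSE
carbamoyl-phosphate,CH4NO5P,pyrimidines,FALSE
dihydroorotate,C5H6N2O4,pyrimidines,FALSE
orotate,C5H4N2O4,pyrimidines,FALSE
CDP-ethanolamine,C11H20N4O11P2,pyrimidines,FALSE
pseudouridine,C9H12N2O6,pyrimidines,FALSE
glucosamine,C6H13NO5,amino_sugars,FALSE
N-acetylglucosamine,C8H15NO6,amino_sugars,TRUE
glucosamine-6-phosphate,C6H14NO8P,amino_sugars,FALSE
N-acetylglucosamine-6-phosphate,C8H16NO9P,amino_sugars,FALSE
N-acetylneuraminate,C11H19NO9,amino_sugars,FALSE
UDP-glucose,C15H24N2O17P2,nucleotide_sugars,FALSE
UDP-N-acetylglucosamine,C17H27N3O17P2,nucleotide_sugars,TRUE
GDP-mannose,C16H25N5O16P2,nucleotide_sugars,FALSE
CMP-N-acetylneuraminate,C20H31N4O16P,nucleotide_sugars,FALSE
nicotinamide,C6H6N2O,nad_metabolism,FALSE
nicotinate,C6H5NO2,nad_metabolism,FALSE
NAD,C21H27N7O14P2,nad_metabolism,TRUE
NADP,C21H28N7O17P3,nad_metabolism,FALSE
NMN,C11H15N2O8P,nad_metabolism,FALSE
nicotinamide-riboside,C11H14N2O5,nad_metabolism,FALSE
putrescine,C4H12N2,polyamines,FALSE
spermidine,C7H19N3,polyamines,TRUE
spermine,C10H26N4,polyamines,FALSE
agmatine,C5H14N4,polyamines,FALSE
N-acetylputrescine,C6H14N2O,polyamines,FALSE
glutathione,C10H17N3O6S,glutathione,TRUE
glutathione-disulfide,C20H32N6O12S2,glutathione,FALSE
gamma-glutamylcysteine,C8H14N2O5S,glutathione,FALSE
ophthalmate,C11H19N3O6,glutathione,FALSE
cysteinylglycine,C5H10N2O3S,glutathione,FALSE
pantothenate,C9H17NO5,vitamins_cofactors,TRUE
folate,C19H19N7O6,vitamins_cofactors,FALSE
thiamine,C12H17N4OS,vitamins_cofactors,FALSE
riboflavin,C17H20N4O6,vitamins_cofactors,FALSE
pyridoxine,C8H11NO3,vitamins_cofactors,FALSE
biotin,C10H16N2O3S,vitamins_cofactors,FALSE
4-aminobenzoate,C7H7NO2,vitamins_cofactors,FALSE
ammonium,NH4,ions,TRUE
nitrate,NO3,ions,FALSE
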