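tracer,nutrient,labelled_atoms,element,proteinogenic
alanine,alanine,1,N,TRUE
arginine,arginine,4,N,TRUE
asparagine,asparagine,2,N,TRUE
aspartate,aspartate,1,N,TRUE
cysteine,cysteine,1,N,TRUE
glutamine,glutamine,2,N,TRUE
glutamate,glutamate,1,N,TRUE
glycine,glycine,1,N,TRUE
histidine,histidine,3,N,TRUE
isoleucine,isoleucine,1,N,TRUE
leucine,leucine,1,N,TRUE
lysine,lysine,2,N,TRUE
methionine,methionine,1,N,TRUE
phenylalanine,phenylalanine,1,N,TRUE
proline,proline,1,N,TRUE
serine,serine,1,N,TRUE
threonine,threonine,1,N,TRUE
tryptophan,tryptophan,2,N,TRUE
tyrosine,tyrosine,1,N,TRUE
valine,valine,1,N,TRUE
taurine,taurine,1,N,FALSE
ornithine,ornithine,2,N,FALSE
citrulline,citrulline,3,N,FALSE
hypoxanthine,hypoxanthine,4,N,FALSE
uridine,uridine,2,N,FALSE
nitrate,nitrate,1,N,FALSE
ammonium,ammonium,1,N,FALSE
urea,urea,2,N,FALSE
urate,urate,4,N,FALSE
glutamine-amide,glutamine,1,N,FALSE
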