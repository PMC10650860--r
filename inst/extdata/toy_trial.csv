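# minimal synthetic example trial: 4 genotypes, N2 + SNI, 2 replicates
genotype,environment,replicate,trait,value
G01,N2,1,GY,182.4
G01,N2,2,GY,176.9
G01,SNI,1,GY,96.1
G01,SNI,2,GY,90.8
G02,N2,1,GY,204.5
G02,N2,2,GY,199.0
G02,SNI,1,GY,58.2
G02,SNI,2,GY,63.9
G03,N2,1,GY,154.3
G03,N2,2,GY,160.6
G03,SNI,1,GY,104.9
G03,SNI,2,GY,99.4
G04,N2,1,GY,221.7
G04,N2,2,GY,214.2
G04,SNI,1,GY,41.5
G04,SNI,2,GY,47.0
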