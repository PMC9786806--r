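taxon,maternal_level,locality,plant_code,fruits,fcss_seeds,fcss_success
C. monogyna,2,MK,MKT,22,10,10
C. monogyna,2,CIC,MONOG1,29,20,18
C. monogyna,2,CIC,MONOG3,28,20,20
C. monogyna,2,CIC,KVP4,26,20,20
C. monogyna,2,BOTZ,BOTZ1,23,20,20
C. monogyna,2,BOTZ,BOTZ2,NA,10,10
C. monogyna,2,KO,KO VETER,NA,10,10
C. monogyna,2,BIEL,BIEL15-3,NA,10,10
C. monogyna,2,DOBRA,DOBRA1,NA,10,10
C. monogyna,2,C,CIERNANT1,NA,10,7
C. kyrtostyla,2,PO,PO1,31,20,18
C. kyrtostyla,2,CIC,KVP1,33,10,10
C. kyrtostyla,2,GOC,GOCAL15-1,12,10,10
C. kyrtostyla,2,GOC,GOCAL15-2,14,10,9
C. kyrtostyla,2,GOC,GOCAL15-3,11,10,10
C. kyrtostyla,2,LIP,LIP15-1,32,20,20
C. kyrtostyla,2,LIP,LIP15-2,28,20,20
C. kyrtostyla,2,LIP,LIP15-5,15,NA,NA
C. kyrtostyla,2,RAZNH,RAZNH15-1,15,10,10
C. kyrtostyla,2,RAZNH,RAZNH15-2,NA,8,5
C. kyrtostyla,3,CIC,1518/11,58,29,29
C. kyrtostyla,3,KAV,kyrtoA,121,5,5
C. rhipidophylla,3,CIC,1447/11,76,5,5
C. rhipidophylla,3,CIC,1453/11,58,47,46
C. subsphaerica,3,HERM,Vyhon3,198,98,97
C. subsphaerica,3,CIC,1445/11,88,18,18
C. subsphaerica,3,CIC,1472/11,103,61,59
C. subsphaerica,3,CIC,1478/11,59,44,44
C. subsphaerica,3,CIC,1531/11,80,34,34
C. subsphaerica,3,CIC,1537/11,62,54,52
C. subsphaerica,3,CIC,1539/11,70,65,63
C. subsphaerica,3,CIC,1521/11,32,20,19
C. subsphaerica,3,CIC,1525/11,54,31,31
C. subsphaerica,3,CIC,1527/11,105,88,88
C. laevigata x C. kyrtostyla,3,HERM,Hurka1,239,114,110
C. kyrtostyla x C. subsphaerica,3,RAZNH,RaznH2,121,104,100
C. subsphaerica x C. laevigata,3,RAZNH,RaznH1,117,100,95
C. laevigata x C. subsphaerica,3,HERM,Sosen3,140,135,133
C. laevigata x C. subsphaerica,3,HERM,Vyhon4,215,73,67
C. laevigata x C. subsphaerica,3,HERM,Vyhon8,87,77,73
C. subsphaerica,4,HERM,PS-Vyh16-1,NA,5,5
C. subsphaerica,4,HERM,PS-Vyh16-2,NA,8,7
C. subsphaerica,4,HERM,Vyhon2,NA,8,8
C. subsphaerica,4,HERM,Vyhon16-16,NA,10,10
C. subsphaerica,4,HERM,Vyhon16-15,NA,17,16
C. subsphaerica,4,RAZNH,RaznH16-3,NA,15,15
C. subsphaerica,4,MAJ,MAJ16-1,NA,27,27
C. subsphaerica,4,MAJ,MAJ16-2,NA,24,22
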