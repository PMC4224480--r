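name	formula	database_id
homocitrulline	C7H15N3O3	HMDB00679
2-hydroxyvaleric acid	C5H10O3	HMDB01863
cystine	C6H12N2O4S2	HMDB00192
aspartic acid	C4H7NO4	HMDB00191
isoleucine	C6H13NO2	HMDB00172
creatinine	C4H7N3O	HMDB00562
serine	C3H7NO3	HMDB00187
4-hydroxyphenyllactic acid	C9H10O4	HMDB00755
citric acid	C6H8O7	HMDB00094
glutamic acid	C5H9NO4	HMDB00148
lactic acid	C3H6O3	HMDB00190
DHEA sulfate	C19H28O5S	HMDB01032
glutaric acid	C5H8O4	HMDB00661
5-aminovaleric acid lactam	C5H9NO	HMDB11749
succinic acid	C4H6O4	HMDB00254
myristic acid	C14H28O2	HMDB00806
heptadecanoic acid	C17H34O2	HMDB02259
3-aminoisobutyric acid	C4H9NO2	HMDB02166
5-hydroxynorvaline	C5H11NO3	HMDB31658
glucose	C6H12O6	HMDB00122
tryptophan	C11H12N2O2	HMDB00929
glycine	C2H5NO2	HMDB00123
taurine	C2H7NO3S	HMDB00251
uric acid	C5H4N4O3	HMDB00289
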