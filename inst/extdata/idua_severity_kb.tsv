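name	class	severities	low_reliability	source_table
Y76C	missense	mild	FALSE	table7
M504T	missense	intermediate	FALSE	table7
V620F	missense	severe	FALSE	table7
R89W	missense	mild	FALSE	table7
L535F	missense	intermediate	FALSE	table7
R628P	missense	severe	FALSE	table7
R89Q	missense	mild,intermediate	FALSE	table7
R619G	missense	intermediate	FALSE	table7
X654C	missense	severe	FALSE	table7
A160D	missense	mild,intermediate	FALSE	table7
W626R	missense	intermediate	FALSE	table7
L421P	missense	unknown	FALSE	table7
C205Y	missense	mild	FALSE	table7
X654G	missense	intermediate	FALSE	table7
L578Q	missense	unknown	FALSE	table7
G219E	missense	mild,intermediate	FALSE	table7
X654R	missense	intermediate,severe	FALSE	table7
G168V	missense	unknown	FALSE	table7
H240R	missense	mild	FALSE	table7
M1T	missense	severe	FALSE	table7
F52L	missense	unknown	FALSE	table7
E276K	missense	mild,intermediate	FALSE	table7
G51D	missense	severe	FALSE	table7
L396P	missense	unknown	FALSE	table7
W306L	missense	mild,intermediate	FALSE	table7
A75T	missense	severe	FALSE	table7
P533R	missense	unknown	FALSE	table7
A319V	missense	mild,intermediate	FALSE	table7
T103P	missense	severe	FALSE	table7
H33P	missense	unknown	FALSE	table7
L346R	missense	mild,intermediate	FALSE	table7
M133I	missense	severe	FALSE	table7
A79V	missense	unknown	FALSE	table7
N348K	missense	mild	TRUE	table7
T141S	missense	severe	FALSE	table7
G197S	missense	unknown	FALSE	table7
N350I	missense	mild,intermediate	FALSE	table7
F177S	missense	severe	FALSE	table7
W41X	nonsense	severe	FALSE	table7
Q380R	missense	mild,intermediate	FALSE	table7
E182D	missense	severe	FALSE	table7
C53X	nonsense	severe	FALSE	table7
R383H	missense	mild,intermediate	FALSE	table7
E182K	missense	severe	FALSE	table7
Q60X	nonsense	severe	FALSE	table7
T388R	missense	mild	FALSE	table7
P183R	missense	severe	FALSE	table7
Q63X	nonsense	severe	FALSE	table7
S423R	missense	mild,intermediate	FALSE	table7
D203N	missense	severe	FALSE	table7
Y64X	nonsense	severe	FALSE	table7
R492P	missense	mild	FALSE	table7
G208D	missense	severe	FALSE	table7
Q70X	nonsense	severe	FALSE	table7
S633L	missense	mild,intermediate	FALSE	table7
G208V	missense	severe	FALSE	table7
Y167X	nonsense	severe	FALSE	table7
M1I	missense	intermediate	FALSE	table7
L218P	missense	severe	FALSE	table7
Y201X	nonsense	severe	FALSE	table7
A75P	missense	intermediate	FALSE	table7
L237R	missense	severe	FALSE	table7
E274X	nonsense	severe	FALSE	table7
H82P	missense	intermediate	FALSE	table7
L238R	missense	severe	FALSE	table7
E299X	nonsense	severe	FALSE	table7
G84R	missense	intermediate	TRUE	table7
I270S	missense	severe	FALSE	table7
Q310X	nonsense	severe	FALSE	table7
E178K	missense	intermediate	FALSE	table7
L308P	missense	severe	FALSE	table7
Y343X	nonsense	severe	FALSE	table7
T179R	missense	intermediate,severe	FALSE	table7
D315Y	missense	severe	FALSE	table7
W402X	nonsense	severe	FALSE	table7
F188L	missense	intermediate	TRUE	table7
A327P	missense	severe	FALSE	table7
E404X	nonsense	severe	FALSE	table7
G197D	missense	intermediate	FALSE	table7
D349N	missense	severe	FALSE	table7
W420X	nonsense	severe	FALSE	table7
L238Q	missense	intermediate	FALSE	table7
D349Y	missense	severe	FALSE	table7
Q561X	nonsense	severe	FALSE	table7
S260F	missense	intermediate	TRUE	table7
R363C	missense	severe	FALSE	table7
Y581X	nonsense	severe	FALSE	table7
G265R	missense	intermediate	FALSE	table7
T366P	missense	severe	FALSE	table7
Q584X	nonsense	severe	FALSE	table7
R363H	missense	intermediate	FALSE	table7
T374N	missense	severe	FALSE	table7
R619X	nonsense	severe	FALSE	table7
T364M	missense	intermediate	FALSE	table7
P385R	missense	severe	FALSE	table7
R621X	nonsense	severe	FALSE	table7
A436P	missense	intermediate	FALSE	table7
R489P	missense	severe	FALSE	table7
W626X	nonsense	severe	FALSE	table7
G409R	missense	severe	FALSE	table7
P496R	missense	severe	FALSE	table7
R628X	nonsense	severe	FALSE	table7
L490P	missense	intermediate	FALSE	table7
P533L	missense	severe	FALSE	table7
P496L	missense	intermediate	FALSE	table7
F602I	missense	severe	FALSE	table7
134del12	deletion_insertion	severe	FALSE	table8
c.1147dupG	deletion_insertion	severe	FALSE	table8
IVS4-1G>A	splicing	intermediate,severe	FALSE	table8
153delC	deletion_insertion	severe	FALSE	table8
c.1166_1171dup	deletion_insertion	severe	FALSE	table8
IVS4+1G>A	splicing	intermediate	FALSE	table8
229del3	deletion_insertion	severe	FALSE	table8
c.1190-1delG	deletion_insertion	severe	FALSE	table8
IVS5-7G>A	splicing	mild	FALSE	table8
252insC	deletion_insertion	severe	FALSE	table8
c.1225dupG	deletion_insertion	severe	FALSE	table8
IVS5+1G>A	splicing	severe	FALSE	table8
c.349delT	deletion_insertion	unknown	FALSE	table8
c.1244-1271del27	deletion_insertion	severe	FALSE	table8
IVS6+1G>C	splicing	severe	FALSE	table8
396insAC	deletion_insertion	mild	TRUE	table8
1251delC	deletion_insertion	severe	FALSE	table8
IVS6+1G>T	splicing	severe	FALSE	table8
468del3	deletion_insertion	severe	FALSE	table8
1277ins9	deletion_insertion	severe	FALSE	table8
IVS7-4G>A	splicing	severe	FALSE	table8
486del6	deletion_insertion	unknown	FALSE	table8
1352delG	deletion_insertion	severe	FALSE	table8
IVS7+2T>C	splicing	unknown	FALSE	table8
c.574delT	deletion_insertion	severe	FALSE	table8
c.1398delC	deletion_insertion	severe	FALSE	table8
IVS8-1G>A	splicing	severe	FALSE	table8
628del5	deletion_insertion	severe	FALSE	table8
c.1589insGC	deletion_insertion	severe	FALSE	table8
IVS8+4G>A	splicing	intermediate	FALSE	table8
c.657dupG	deletion_insertion	severe	FALSE	table8
c.1593delG	deletion_insertion	intermediate	TRUE	table8
IVS8+5G>A	splicing	intermediate,severe	FALSE	table8
668insGCG	deletion_insertion	severe	FALSE	table8
1702delG	deletion_insertion	severe	FALSE	table8
IVS9+1G>T	splicing	severe	FALSE	table8
682insAC	deletion_insertion	severe	FALSE	table8
1783del11	deletion_insertion	severe	FALSE	table8
IVS9+2T>G	splicing	unknown	FALSE	table8
702ins10del22	deletion_insertion	severe	FALSE	table8
c.1805delTinsGAACA	deletion_insertion	severe	FALSE	table8
IVS11-G>T	splicing	severe	FALSE	table8
704ins5	deletion_insertion	severe	FALSE	table8
1839del29	deletion_insertion	severe	FALSE	table8
IVS11+5G>A	splicing	severe	FALSE	table8
740delC	deletion_insertion	severe	FALSE	table8
1902del2	deletion_insertion	severe	FALSE	table8
IVS11+5G>C	splicing	severe	FALSE	table8
747delG	deletion_insertion	severe	FALSE	table8
c.1918_1927del10	deletion_insertion	intermediate	TRUE	table8
3308del12	splicing	intermediate	FALSE	table8
755del5	deletion_insertion	severe	FALSE	table8
1995del11	deletion_insertion	intermediate	TRUE	table8
IVS12+1G>A	splicing	severe	FALSE	table8
c.826_828del3	deletion_insertion	severe	FALSE	table8
D444/445	deletion_insertion	mild	FALSE	table8
IVS12+2T>G	splicing	severe	FALSE	table8
c.854delC	deletion_insertion	severe	FALSE	table8
c.1-2C>G	splicing	severe	FALSE	table8
IVS12+2T>A	splicing	unknown	FALSE	table8
c.883dupC	deletion_insertion	severe	FALSE	table8
IVS2-1G>C	splicing	severe	FALSE	table8
IVS12+3G>C	splicing	severe	FALSE	table8
c.956_972+9delinsTA	deletion_insertion	severe	FALSE	table8
IVS2-3C>G	splicing	unknown	FALSE	table8
IVS12+4C>T	splicing	intermediate	FALSE	table8
964delC	deletion_insertion	severe	FALSE	table8
IVS2+1G>A	splicing	intermediate	FALSE	table8
IVS12+5G>A	splicing	severe	FALSE	table8
974ins12	deletion_insertion	mild	FALSE	table8
IVS2+6C>T	splicing	severe	FALSE	table8
IVS12+5G>C	splicing	unknown	FALSE	table8
c.1045_1047del3	deletion_insertion	severe	FALSE	table8
IVS3-2A>G	splicing	severe	FALSE	table8
IVS12+6T>A	splicing	severe	FALSE	table8
1132del6	deletion_insertion	severe	FALSE	table8
IVS3+1G>A	splicing	severe	FALSE	table8
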