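drug_code,name,class,generation,rule_type,parameter
levodopa,Levodopa (immediate release),pd_drug,,factor,1
amantadine,Amantadine,pd_drug,,factor,1
pramipexole,Pramipexole,pd_drug,,factor,100
ropinirole,Ropinirole,pd_drug,,factor,20
rasagiline,Rasagiline,pd_drug,,factor,100
selegiline,Selegiline (oral),pd_drug,,factor,10
entacapone,Entacapone,pd_drug,,levodopa_fraction,0.33
benserazide,Benserazide,pd_drug,,none,0
carbidopa,Carbidopa,pd_drug,,none,0
azelastine,Azelastine,antihistamine,2,none,0
bepotastine,Bepotastine,antihistamine,2,none,0
cetirizine,Cetirizine,antihistamine,2,none,0
chlorpheniramine,Chlorpheniramine,antihistamine,1,none,0
clemastine,Clemastine,antihistamine,1,none,0
desloratadine,Desloratadine,antihistamine,2,none,0
dimenhydrinate,Dimenhydrinate,antihistamine,1,none,0
ebastine,Ebastine,antihistamine,2,none,0
fexofenadine,Fexofenadine,antihistamine,2,none,0
hydroxyzine,Hydroxyzine,antihistamine,1,none,0
ketotifen,Ketotifen,antihistamine,2,none,0
levocetirizine,Levocetirizine,antihistamine,2,none,0
loratadine,Loratadine,antihistamine,2,none,0
mizolastine,Mizolastine,antihistamine,2,none,0
olopatadine,Olopatadine,antihistamine,2,none,0
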