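meniscectomy
chondroplasty
synovectomy
tenotomy
tenolysis
osteoplasty
osteotomy
arthrodesis
arthroplasty
fasciotomy
capsulorrhaphy
tenodesis
bursectomy
sequestrectomy
epiphysiodesis
hemiepiphysiodesis
osteochondroplasty
femoroplasty
acetabuloplasty
labralplasty
meniscoplasty
tuberoplasty
coracoplasty
acromioplasty
claviculectomy
patellectomy
fabellectomy
styloidectomy
radiectomy
ulnectomy
carpectomy
metacarpectomy
phalangectomy
talectomy
calcanectomy
naviculectomy
cuboidectomy
cuneiformectomy
sesamoidectomy
hallux
cheilectomy
exostectomy
condylectomy
trochleoplasty
coronoidectomy
olecranonplasty
epicondylectomy
capitellum
trochlea
chondrectomy
osteectomy
arthrectomy
fasciectomy
capsulectomy
tendectomy
labrectomy
ligectomy
myelectomy
neurectomy
vasculectomy
fibulectomy
tibiectomy
femorectomy
humerectomy
tarsectomy
metatarsectomy
acromiectomy
scapulectomy
vertebrectomy
costectomy
sternectomy
pelvectomy
iliectomy
ischiectomy
pubectomy
sacrectomy
coccygectomy
meniscotomy
chondrotomy
synovotomy
arthrotomy
capsulotomy
tendotomy
bursotomy
labrotomy
ligotomy
myelotomy
neurotomy
vasculotomy
fibulotomy
tibiotomy
femorotomy
humerotomy
radiotomy
ulnotomy
carpotomy
tarsotomy
metatarsotomy
phalangotomy
patellotomy
acromiotomy
claviculotomy
scapulotomy
vertebrotomy
costotomy
sternotomy
pelvotomy
iliotomy
ischiotomy
pubotomy
sacrotomy
coccygotomy
synovoplasty
fascioplasty
capsuloplasty
tendoplasty
bursoplasty
labroplasty
ligoplasty
myeloplasty
neuroplasty
vasculoplasty
fibuloplasty
tibioplasty
humeroplasty
radioplasty
ulnoplasty
carpoplasty
tarsoplasty
metatarsoplasty
phalangoplasty
patelloplasty
claviculoplasty
scapuloplasty
vertebroplasty
costoplasty
sternoplasty
pelvoplasty
ilioplasty
ischioplasty
puboplasty
sacroplasty
coccygoplasty
meniscodesis
chondrodesis
synovodesis
osteodesis
fasciodesis
capsulodesis
tendodesis
bursodesis
labrodesis
ligodesis
myelodesis
neurodesis
vasculodesis
fibulodesis
tibiodesis
femorodesis
humerodesis
radiodesis
ulnodesis
carpodesis
tarsodesis
metatarsodesis
phalangodesis
patellodesis
acromiodesis
claviculodesis
scapulodesis
vertebrodesis
costodesis
sternodesis
pelvodesis
iliodesis
ischiodesis
pubodesis
sacrodesis
coccygodesis
meniscorrhaphy
chondrorrhaphy
synovorrhaphy
osteorrhaphy
arthrorrhaphy
fasciorrhaphy
tendorrhaphy
bursorrhaphy
labrorrhaphy
ligorrhaphy
myelorrhaphy
neurorrhaphy
vasculorrhaphy
fibulorrhaphy
tibiorrhaphy
femororrhaphy
humerorrhaphy
radiorrhaphy
ulnorrhaphy
carporrhaphy
tarsorrhaphy
metatarsorrhaphy
phalangorrhaphy
patellorrhaphy
acromiorrhaphy
claviculorrhaphy
scapulorrhaphy
vertebrorrhaphy
costorrhaphy
sternorrhaphy
pelvorrhaphy
iliorrhaphy
ischiorrhaphy
puborrhaphy
sacrorrhaphy
coccygorrhaphy
meniscolysis
chondrolysis
synovolysis
osteolysis
arthrolysis
fasciolysis
capsulolysis
tendolysis
bursolysis
labrolysis
ligolysis
myelolysis
neurolysis
vasculolysis
fibulolysis
tibiolysis
femorolysis
humerolysis
radiolysis
ulnolysis
carpolysis
tarsolysis
metatarsolysis
phalangolysis
patellolysis
acromiolysis
claviculolysis
scapulolysis
vertebrolysis
costolysis
sternolysis
pelvolysis
iliolysis
ischiolysis
pubolysis
sacrolysis
coccygolysis
meniscopexy
chondropexy
synovopexy
osteopexy
arthropexy
fasciopexy
capsulopexy
tendopexy
bursopexy
labropexy
ligopexy
myelopexy
neuropexy
vasculopexy
fibulopexy
tibiopexy
femoropexy
humeropexy
radiopexy
ulnopexy
carpopexy
tarsopexy
metatarsopexy
phalangopexy
patellopexy
acromiopexy
claviculopexy
scapulopexy
vertebropexy
costopexy
sternopexy
pelvopexy
iliopexy
ischiopexy
pubopexy
sacropexy
coccygopexy
meniscoscopy
chondroscopy
synovoscopy
osteoscopy
arthroscopy
fascioscopy
capsuloscopy
tendoscopy
bursoscopy
labroscopy
ligoscopy
myeloscopy
neuroscopy
vasculoscopy
fibuloscopy
tibioscopy
femoroscopy
humeroscopy
radioscopy
ulnoscopy
carposcopy
tarsoscopy
metatarsoscopy
phalangoscopy
patelloscopy
acromioscopy
claviculoscopy
scapuloscopy
vertebroscopy
costoscopy
sternoscopy
pelvoscopy
ilioscopy
ischioscopy
puboscopy
sacroscopy
coccygoscopy
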